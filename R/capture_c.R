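# ---- Capture-C viewpoint profiles ----------------------------------------

#' Percent reads per promoter (PRPP) normalization
#'
#' `PRPP = N / cov * nprom * 100` per restriction fragment, where `N` is
#' the fragment's read count, `cov` the total coverage of reads aligned to
#' captured promoters in the sample and `nprom` the number of promoters
#' captured. PRPP is exactly invariant to sequencing depth when counts
#' scale with `cov`. An optional x1000 display scaling gives mPRPP.
#'
#' @param profile tibble with columns `frag` and `count` (one viewpoint).
#' @param cov total captured-promoter coverage of the sample (> 0).
#' @param nprom number of promoters captured (>= 1).
#' @param milli also add an `mprpp` column (`prpp * 1000`).
#' @return The profile with a `prpp` (and optionally `mprpp`) column;
#'   `cov` and `nprom` stored as attributes.
#' @export
prpp_normalize <- function(profile, cov, nprom, milli = FALSE) {
  stopifnot(cov > 0, nprom >= 1)
  profile <- tibble::as_tibble(profile)
  profile$prpp <- profile$count / cov * nprom * 100
  if (milli) profile$mprpp <- profile$prpp * 1000
  attr(profile, "cov") <- cov
  attr(profile, "nprom") <- nprom
  profile
}

#' Score viewpoint interactions against a distance-decay background
#'
#' A Poisson distance-decay scorer behind the standard "score >= 5"
#' interface: the expected count per fragment is a log-log linear fit of
#' count against `1 + |frag - viewpoint|` (the top 1% of fragments by count
#' are excluded from the fit so true peaks do not inflate the background),
#' and the score is `-log10` of the upper-tail Poisson p-value. Scores are
#' monotone in the observed count at fixed expected.
#'
#' @param profile tibble with `frag` and `count`.
#' @param viewpoint viewpoint fragment index.
#' @return The profile with `bg_expected`, `p_value` and `score` columns.
#' @export
score_interactions <- function(profile, viewpoint) {
  profile <- tibble::as_tibble(profile)
  d <- 1 + abs(profile$frag - viewpoint)
  fit_set <- profile$count <= stats::quantile(profile$count, 0.99) &
             profile$count > 0 & profile$frag != viewpoint
  if (sum(fit_set) < 3) stop("too few fragments to fit a background", call. = FALSE)
  fit <- stats::lm(log(count) ~ log(d), data = cbind(profile, d = d)[fit_set, ])
  mu <- exp(stats::predict(fit, newdata = data.frame(d = d)))
  pv <- stats::ppois(profile$count - 1, mu, lower.tail = FALSE)
  profile$bg_expected <- mu
  profile$p_value <- pv
  profile$score <- -log10(pmax(pv, 1e-300))
  profile$score[profile$frag == viewpoint] <- 0
  profile
}

#' Merge significant fragments into interaction peaks
#'
#' Fragments with score at least `score_min` are chained while consecutive
#' significant fragments are closer than `merge_dist` fragments (strict
#' `<`; a gap of exactly `merge_dist` starts a new peak). The summit is the
#' local maximum in the control sample when the peak has control signal,
#' otherwise in the sample where it was found; ties break toward the
#' fragment nearest the viewpoint. Idempotent and order-independent.
#'
#' @param scored scored profile (from [score_interactions()]) with a
#'   `prpp` or `count` column used for the summit.
#' @param viewpoint viewpoint fragment index (for summit tie-breaking).
#' @param score_min significance threshold on `score`.
#' @param merge_dist merge distance in fragments.
#' @param control optional control profile (tibble `frag` + `prpp`/`count`)
#'   in which summits are preferentially located.
#' @return A tibble of peaks: `start_frag`, `end_frag`, `n_frags`,
#'   `summit_frag`, `max_score`.
#' @export
merge_peaks <- function(scored, viewpoint, score_min = 5, merge_dist = 10,
                        control = NULL) {
  scored <- tibble::as_tibble(scored)
  sig <- sort(scored$frag[scored$score >= score_min])
  if (length(sig) == 0) {
    return(tibble::tibble(start_frag = integer(), end_frag = integer(),
                          n_frags = integer(), summit_frag = integer(),
                          max_score = numeric()))
  }
  grp <- cumsum(c(1L, as.integer(diff(sig) >= merge_dist)))
  summit_col <- function(df) {
    if ("prpp" %in% names(df)) df$prpp else df$count
  }
  purrr::map(split(sig, grp), function(frs) {
    span <- min(frs):max(frs)
    src <- NULL
    if (!is.null(control)) {
      ctl <- control[control$frag %in% span, ]
      if (nrow(ctl) > 0 && any(summit_col(ctl) > 0)) src <- ctl
    }
    if (is.null(src)) src <- scored[scored$frag %in% span, ]
    v <- summit_col(src)
    best <- which(v == max(v))
    if (length(best) > 1) best <- best[which.min(abs(src$frag[best] - viewpoint))]
    tibble::tibble(
      start_frag = min(frs), end_frag = max(frs), n_frags = length(frs),
      summit_frag = src$frag[best],
      max_score = max(scored$score[scored$frag %in% frs])
    )
  }) |>
    dplyr::bind_rows()
}

#' Summit-aligned aggregate interaction profiles
#'
#' Extracts a window of `+/- window_frags` fragments around each peak
#' summit, normalizes every condition to the control summit PRPP for that
#' peak, and averages within distance groups. An optional running mean
#' (`smooth_frags`) reproduces display smoothing over restriction
#' fragments.
#'
#' @param profiles named list of PRPP profiles (tibbles `frag`, `prpp`),
#'   one per condition; must include `control`.
#' @param peaks peak table from [merge_peaks()].
#' @param viewpoint viewpoint fragment index.
#' @param distance_groups optional integer vector (one per peak) of group
#'   labels, e.g. distance quantiles; default one group.
#' @param window_frags half-width of the summit-aligned window.
#' @param smooth_frags if > 1, running-mean smoothing width.
#' @return A tibble with `condition`, `group`, `offset` (fragments from
#'   summit) and `mean_rel_prpp` (relative to the control summit); empty
#'   groups are dropped with a message.
#' @export
aggregate_profiles <- function(profiles, peaks, viewpoint,
                               distance_groups = NULL, window_frags = 50,
                               smooth_frags = 1) {
  stopifnot("control" %in% names(profiles))
  if (is.null(distance_groups)) distance_groups <- rep(1L, nrow(peaks))
  stopifnot(length(distance_groups) == nrow(peaks))
  ctl <- profiles$control
  out <- list()
  for (cond in names(profiles)) {
    prof <- profiles[[cond]]
    for (k in seq_len(nrow(peaks))) {
      s <- peaks$summit_frag[k]
      ctl_summit <- ctl$prpp[match(s, ctl$frag)]
      if (is.na(ctl_summit) || ctl_summit == 0) next
      off <- (-window_frags):window_frags
      vals <- prof$prpp[match(s + off, prof$frag)] / ctl_summit
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cond, group = distance_groups[k], peak = k,
        offset = off, rel_prpp = vals)
    }
  }
  agg <- dplyr::bind_rows(out) |>
    dplyr::group_by(.data$condition, .data$group, .data$offset) |>
    dplyr::summarise(mean_rel_prpp = mean(.data$rel_prpp, na.rm = TRUE),
                     n_peaks = dplyr::n(), .groups = "drop")
  empty <- setdiff(unique(distance_groups), unique(agg$group))
  if (length(empty) > 0) {
    message("empty distance groups excluded: ", paste(empty, collapse = ", "))
  }
  if (smooth_frags > 1) {
    agg <- agg |>
      dplyr::group_by(.data$condition, .data$group) |>
      dplyr::arrange(.data$offset, .by_group = TRUE) |>
      dplyr::mutate(mean_rel_prpp = stats::filter(
        .data$mean_rel_prpp, rep(1 / smooth_frags, smooth_frags),
        sides = 2) |> as.numeric()) |>
      dplyr::ungroup()
  }
  agg
}

#' Plot aggregate viewpoint profiles
#'
#' @param agg output of [aggregate_profiles()].
#' @return A ggplot line plot per condition, faceted by distance group.
#' @export
plot_capture_aggregate <- function(agg) {
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$offset, y = .data$mean_rel_prpp,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "fragments from summit",
                  y = "PRPP relative to control summit") +
    ggplot2::theme_minimal()
}
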