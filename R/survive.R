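#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), computed with
#' \code{survival::survfit}. With censored-only input the curve is
#' identically 1 (no event times).
#'
#' @param times Non-negative follow-up times (days).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Object of class \code{"km_curve"}: data.frame with one row per
#'   distinct event time (columns \code{time}, \code{survival},
#'   \code{at_risk}, \code{n_events}) plus attributes \code{n_total} and
#'   \code{n_events_total}.
#' @export
km_estimate <- function(times, events) {
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]; events <- events[keep]
  if (length(times) == 0L) stop("no usable subject")
  if (any(times < 0)) stop("negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  is_event <- fit$n.event > 0
  out <- data.frame(time = fit$time[is_event],
                    survival = fit$surv[is_event],
                    at_risk = fit$n.risk[is_event],
                    n_events = fit$n.event[is_event])
  attr(out, "n_total") <- length(times)
  attr(out, "n_events_total") <- sum(events)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted, Mantel-Haenszel) log-rank chi-square comparing k
#' groups, with k - 1 degrees of freedom and hypergeometric tie handling;
#' computed with \code{survival::survdiff}.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Group label per subject (factor or character).
#' @return List with \code{chi2}, \code{df}, \code{p_value}, and per-group
#'   \code{observed} and \code{expected} event counts.
#' @export
logrank_test <- function(times, events, group) {
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 2L) stop("log-rank needs >= 2 non-empty groups")
  if (any(times < 0)) stop("negative follow-up time")
  if (sum(events) == 0) stop("log-rank test undefined: zero events")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  df <- length(sd$n) - 1L
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = as.vector(sd$obs), expected = as.vector(sd$exp),
       groups = levels(group), n = as.vector(sd$n))
}

#' Survival contrasts between EMT groups for one endpoint
#'
#' Runs the three-group log-rank test and the pairwise high-vs-low test for
#' one endpoint (OS or PFI), and returns per-group Kaplan-Meier curves.
#' Records with a missing time or event are dropped per-endpoint.
#'
#' @param clinical A \code{\link{clinical_table}}.
#' @param groups An \code{"emt_groups"} assignment.
#' @param endpoint \code{"os"} or \code{"pfi"}.
#' @return List with \code{endpoint}, \code{logrank_3group},
#'   \code{logrank_high_vs_low} and \code{km} (named list of
#'   \code{"km_curve"} per EMT group).
#' @export
survival_by_emt_group <- function(clinical, groups, endpoint = c("os", "pfi")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  idx <- match(groups$sample, clinical$sample)
  tm <- clinical[[tcol]][idx]; ev <- clinical[[ecol]][idx]
  g <- groups$group
  keep <- !is.na(tm) & !is.na(ev)
  tm <- tm[keep]; ev <- ev[keep]; g <- droplevels(g[keep])
  if (length(tm) == 0L) stop("no usable ", toupper(endpoint), " record")
  km <- lapply(split(seq_along(tm), g), function(ii) km_estimate(tm[ii], ev[ii]))
  lr3 <- tryCatch(logrank_test(tm, ev, g), error = function(e) NULL)
  hl <- g %in% c("high", "low")
  lr2 <- tryCatch(logrank_test(tm[hl], ev[hl], g[hl]), error = function(e) NULL)
  list(endpoint = endpoint, km = km, logrank_3group = lr3,
       logrank_high_vs_low = lr2, n_used = length(tm))
}
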