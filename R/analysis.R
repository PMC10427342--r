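#' E-E connection fraction
#'
#' Number of existing connections divided by the number of possible
#' off-diagonal pairs, `N (N - 1)`.
#'
#' @param mask Square binary connectivity matrix with zero diagonal (a
#'   `"sorn_network"` is also accepted).
#' @return Fraction in `[0, 1]`.
#' @export
connection_fraction <- function(mask) {
  if (inherits(mask, "sorn_network")) mask <- mask$c_ee
  if (nrow(mask) != ncol(mask)) stop("mask must be square", call. = FALSE)
  if (any(diag(mask) != 0))
    stop("mask has nonzero diagonal (self-connections)", call. = FALSE)
  n <- nrow(mask)
  sum(mask != 0) / (n * (n - 1))
}

#' Write / read a structural event log
#'
#' Tab-separated columns `t`, `kind`, `i`, `j`, `w` (weight at death,
#' initial weight at birth).
#'
#' @param events Event data frame from [train()] or [structural_step()].
#' @param path File path.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "integer",
                                   "integer", "numeric"))
}

#' Replay a structural event log over an initial mask
#'
#' Applies births and deaths in time order; used to check log integrity
#' (the replayed mask must equal the final mask of the run).
#'
#' @param initial_mask Binary mask at the start of the log.
#' @param events Event data frame.
#' @return The replayed mask.
#' @export
replay_events <- function(initial_mask, events) {
  mask <- initial_mask
  if (nrow(events) == 0) return(mask)
  events <- events[order(events$t), , drop = FALSE]
  for (k in seq_len(nrow(events))) {
    i <- events$i[k]; j <- events$j[k]
    if (events$kind[k] == "birth") {
      if (mask[i, j] != 0) stop("birth on an existing connection: log corrupt",
                                call. = FALSE)
      mask[i, j] <- 1
    } else {
      if (mask[i, j] != 1) stop("death without matching connection: log corrupt",
                                call. = FALSE)
      mask[i, j] <- 0
    }
  }
  mask
}

#' Connection lifecycles
#'
#' Matches every birth event to the next death of the same connection and
#' returns the duration in steps. Connections still alive at `horizon` are
#' right-censored: they are flagged and, by default, excluded from
#' downstream power-law fitting.
#'
#' @param events Event data frame (columns `t`, `kind`, `i`, `j`).
#' @param horizon Last observed step; defaults to the last event time.
#' @return Data frame with `i`, `j`, `birth`, `death` (`NA` if censored),
#'   `duration` (censored ones measured to `horizon`), `censored`.
#' @export
lifecycles <- function(events, horizon = NULL) {
  if (nrow(events) == 0)
    return(data.frame(i = integer(0), j = integer(0), birth = integer(0),
                      death = integer(0), duration = numeric(0),
                      censored = logical(0)))
  if (is.null(horizon)) horizon <- max(events$t)
  events <- events[order(events$t), , drop = FALSE]
  key <- paste(events$i, events$j, sep = ",")
  open_birth <- new.env(parent = emptyenv())
  out <- list()
  n_out <- 0L
  for (k in seq_len(nrow(events))) {
    kk <- key[k]
    if (events$kind[k] == "birth") {
      assign(kk, events$t[k], envir = open_birth)
    } else {
      if (exists(kk, envir = open_birth)) {
        b <- get(kk, envir = open_birth)
        rm(list = kk, envir = open_birth)
        n_out <- n_out + 1L
        out[[n_out]] <- c(events$i[k], events$j[k], b, events$t[k])
      }
      # deaths of connections existing since initialization carry no birth
    }
  }
  closed <- if (n_out > 0) {
    m <- do.call(rbind, out)
    data.frame(i = m[, 1], j = m[, 2], birth = m[, 3], death = m[, 4],
               duration = m[, 4] - m[, 3], censored = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), birth = integer(0),
               death = integer(0), duration = numeric(0),
               censored = logical(0))
  }
  open_keys <- ls(envir = open_birth)
  if (length(open_keys) > 0) {
    ij <- do.call(rbind, strsplit(open_keys, ","))
    births <- vapply(open_keys, get, numeric(1), envir = open_birth)
    open <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                       birth = as.integer(births), death = NA_integer_,
                       duration = horizon - births, censored = TRUE)
    closed <- rbind(closed, open)
  }
  rownames(closed) <- NULL
  closed
}

#' Maximum-likelihood lognormal fit of synaptic weights
#'
#' Fits a lognormal distribution to the positive weights and reports the
#' Kolmogorov-Smirnov distance between the sample and the fitted
#' distribution. Degenerate samples (all weights equal) are flagged rather
#' than fitted.
#'
#' @param weights Positive weights (zeros must be excluded upstream).
#' @return List of class `"distribution_fit"` with `family`, `params`
#'   (`meanlog`, `sdlog`), `gof` (KS distance), `n_samples`, `degenerate`.
#' @export
fit_lognormal <- function(weights) {
  weights <- as.numeric(weights)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (length(weights) < 10)
    stop("insufficient data: need at least 10 positive weights",
         call. = FALSE)
  if (stats::sd(log(weights)) < 1e-12) {
    fit <- list(family = "lognormal",
                params = c(meanlog = mean(log(weights)), sdlog = 0),
                gof = NA_real_, n_samples = length(weights),
                degenerate = TRUE)
    class(fit) <- "distribution_fit"
    return(fit)
  }
  fd <- fitdistrplus::fitdist(weights, "lnorm")
  ks <- suppressWarnings(
    stats::ks.test(weights, "plnorm",
                   meanlog = fd$estimate[["meanlog"]],
                   sdlog = fd$estimate[["sdlog"]]))
  fit <- list(family = "lognormal",
              params = c(meanlog = fd$estimate[["meanlog"]],
                         sdlog = fd$estimate[["sdlog"]]),
              gof = unname(ks$statistic), n_samples = length(weights),
              degenerate = FALSE)
  class(fit) <- "distribution_fit"
  fit
}

# Hurwitz zeta by truncated sum plus Euler-Maclaurin tail.
hurwitz_zeta <- function(alpha, xmin, k_direct = 1000) {
  k <- 0:(k_direct - 1)
  head_sum <- sum((xmin + k)^(-alpha))
  a <- xmin + k_direct
  tail <- a^(1 - alpha) / (alpha - 1) + 0.5 * a^(-alpha) +
    alpha * a^(-alpha - 1) / 12
  head_sum + tail
}

#' Maximum-likelihood discrete power-law fit of connection lifetimes
#'
#' Fits `p(x) = x^(-alpha) / zeta(alpha, xmin)` to integer durations by
#' maximum likelihood, choosing the lower cutoff `xmin` that minimizes the
#' Kolmogorov-Smirnov distance between the tail sample and the fitted
#' distribution (Clauset-style cutoff selection).
#'
#' @param lifetimes Positive integer durations (censored ones excluded
#'   upstream), at least 50.
#' @param xmins Candidate lower cutoffs; defaults to the unique sample
#'   values up to the point that keeps at least 10 tail observations.
#' @return `"distribution_fit"` with `params` (`alpha`, `xmin`), `gof`
#'   (KS distance over the tail), `n_samples` (tail size), `degenerate`.
#' @export
fit_powerlaw <- function(lifetimes, xmins = NULL) {
  x <- as.numeric(lifetimes)
  if (length(x) < 50)
    stop("insufficient data: need at least 50 lifetimes", call. = FALSE)
  if (any(x < 1) || any(x != round(x)))
    stop("lifetimes must be positive integers", call. = FALSE)
  if (length(unique(x)) < 2) {
    fit <- list(family = "powerlaw", params = c(alpha = NA_real_,
                                                xmin = min(x)),
                gof = NA_real_, n_samples = length(x), degenerate = TRUE)
    class(fit) <- "distribution_fit"
    return(fit)
  }
  if (is.null(xmins)) {
    u <- sort(unique(x))
    xmins <- u[vapply(u, function(v) sum(x >= v) >= 10, logical(1))]
    if (length(xmins) > 50) xmins <- xmins[seq_len(50)]
  }
  best <- NULL
  for (xm in xmins) {
    tail_x <- x[x >= xm]
    if (length(unique(tail_x)) < 2) next
    nll <- function(alpha)
      length(tail_x) * log(hurwitz_zeta(alpha, xm)) +
        alpha * sum(log(tail_x))
    opt <- stats::optimize(nll, interval = c(1.01, 6))
    alpha <- opt$minimum
    # empirical vs fitted CDF over the observed tail support
    zs <- hurwitz_zeta(alpha, xm)
    support <- xm:max(tail_x)
    pmf <- support^(-alpha) / zs
    cdf_fit <- cumsum(pmf)
    cdf_emp <- stats::ecdf(tail_x)(support)
    ks <- max(abs(cdf_emp - cdf_fit))
    if (is.null(best) || ks < best$gof)
      best <- list(alpha = alpha, xmin = xm, gof = ks,
                   n = length(tail_x))
  }
  if (is.null(best)) {
    fit <- list(family = "powerlaw",
                params = c(alpha = NA_real_, xmin = NA_real_),
                gof = NA_real_, n_samples = length(x), degenerate = TRUE)
  } else {
    fit <- list(family = "powerlaw",
                params = c(alpha = best$alpha, xmin = best$xmin),
                gof = best$gof, n_samples = best$n, degenerate = FALSE)
  }
  class(fit) <- "distribution_fit"
  fit
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("<distribution_fit> %s (n = %d)%s\n", x$family, x$n_samples,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  if (!is.na(x$gof)) cat(sprintf("  KS distance: %.4f\n", x$gof))
  invisible(x)
}

#' Survival of connections by synaptic strength
#'
#' Bins a cohort of connections (observed at a reference time with their
#' weights) into weight quantiles and computes the fraction of each bin
#' still alive at the horizon, plus the Spearman rank correlation between
#' bin strength and survival — positive when stronger connections are more
#' stable.
#'
#' @param weights Cohort weights at the reference time.
#' @param survived Logical: alive at the horizon.
#' @param n_bins Number of quantile bins (default 5).
#' @return List with `table` (per-bin median weight, size, survival
#'   fraction) and `rank_correlation`.
#' @export
survival_by_strength <- function(weights, survived, n_bins = 5) {
  if (length(weights) == 0) stop("empty cohort", call. = FALSE)
  if (length(weights) != length(survived))
    stop("weights and survival flags differ in length", call. = FALSE)
  qs <- stats::quantile(weights, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(weights, breaks = unique(qs), labels = FALSE,
             include.lowest = TRUE)
  tab <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(bin = b,
               median_weight = stats::median(weights[bin == b]),
               n = sum(bin == b),
               survival = mean(survived[bin == b]))
  }))
  rho <- if (nrow(tab) > 1 && stats::sd(tab$survival) > 0)
    stats::cor(tab$median_weight, tab$survival, method = "spearman")
  else NA_real_
  list(table = tab, rank_correlation = rho)
}

#' Plot the synaptic weight distribution with its lognormal fit
#'
#' Histogram of the positive E-E weights on log-spaced bins with the
#' fitted lognormal density overlaid. Draws on the active graphics device;
#' wrap in [grDevices::png()]/[grDevices::svg()] to write a file.
#'
#' @param network A `"sorn_network"` (or a numeric vector of weights).
#' @param fit Optional `"distribution_fit"` from [fit_lognormal()];
#'   computed if missing.
#' @return The fit, invisibly.
#' @export
plot_weight_distribution <- function(network, fit = NULL) {
  w <- if (inherits(network, "sorn_network"))
    network$w_ee[network$c_ee == 1 & network$w_ee > 0]
  else as.numeric(network[network > 0])
  if (is.null(fit)) fit <- fit_lognormal(w)
  breaks <- exp(seq(log(min(w)), log(max(w)), length.out = 31))
  h <- graphics::hist(w, breaks = breaks, plot = FALSE)
  graphics::plot(h$mids, h$density, log = "x", type = "h", lwd = 6,
                 lend = "butt", col = "steelblue",
                 main = "Synaptic weight distribution",
                 xlab = "weight", ylab = "density")
  if (!isTRUE(fit$degenerate)) {
    xs <- exp(seq(log(min(w)), log(max(w)), length.out = 200))
    graphics::lines(xs, stats::dlnorm(xs, fit$params[["meanlog"]],
                                      fit$params[["sdlog"]]),
                    col = "red", lwd = 2)
  }
  invisible(fit)
}

#' Plot the connection-lifecycle distribution with its power-law fit
#'
#' Empirical complementary CDF of the (non-censored) lifecycle durations
#' on log-log axes, with the fitted power-law tail overlaid.
#'
#' @param lifetimes Positive integer durations (e.g.
#'   `lifecycles(events)$duration` of the non-censored rows).
#' @param fit Optional `"distribution_fit"` from [fit_powerlaw()];
#'   computed if missing.
#' @return The fit, invisibly.
#' @export
plot_lifecycle_distribution <- function(lifetimes, fit = NULL) {
  x <- sort(as.numeric(lifetimes))
  if (is.null(fit)) fit <- fit_powerlaw(x)
  ccdf <- 1 - (seq_along(x) - 1) / length(x)
  graphics::plot(x, ccdf, log = "xy", pch = 16, cex = 0.6,
                 col = "steelblue", main = "Connection lifecycle distribution",
                 xlab = "lifetime (steps)", ylab = "P(lifetime >= x)")
  if (!isTRUE(fit$degenerate)) {
    alpha <- fit$params[["alpha"]]; xm <- fit$params[["xmin"]]
    p_tail <- mean(x >= xm)
    xs <- exp(seq(log(xm), log(max(x)), length.out = 100))
    # discrete power-law tail: P(X >= x) ~ zeta(alpha, x)/zeta(alpha, xmin)
    ys <- vapply(xs, function(v)
      p_tail * hurwitz_zeta(alpha, ceiling(v)) / hurwitz_zeta(alpha, xm),
      numeric(1))
    graphics::lines(xs, ys, col = "red", lwd = 2)
  }
  invisible(fit)
}
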