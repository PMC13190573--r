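# Region-intrinsic neuron detection: completeness thresholding from
# synapse-count distributions, region fractions, the strict > 85% rule,
# type completion, and the pre/post fraction curve fit.

#' Estimate the completeness threshold from per-fragment synapse counts
#'
#' Reconstructed datasets mix partially-traced fragments with well-traced
#' neurons; their pooled synapse-count distribution is bimodal and the valley
#' between the two modes separates the populations.
#'
#' Two operationalisations are provided. `"valley"` smooths the distribution
#' of `log10(count + 1)` with a Gaussian kernel (Scott's bandwidth,
#' `sd * n^(-1/5)`) and places the threshold at the density minimum between
#' the two largest modes. `"turning_point"` fits a two-segment piecewise
#' linear model to the log-log count-frequency relation and places the
#' threshold at the breakpoint between the weak (fragment) and strong
#' (well-traced) regimes.
#'
#' @param counts non-negative per-fragment synapse counts (>= 100 values).
#' @param method `"valley"` or `"turning_point"`.
#' @param n_grid density/breakpoint grid resolution.
#' @return an object of class `completeness_threshold`: list with `value`
#'   (synapse count, `NA` if not found), `found`, `method`, `diagnostics`
#'   (mode locations and density/fit summaries).
#' @export
estimate_completeness_threshold <- function(counts,
                                            method = c("valley", "turning_point"),
                                            n_grid = 512L) {
  method <- match.arg(method)
  stopifnot(length(counts) >= 100L, all(counts >= 0))
  z <- log10(counts + 1)
  not_found <- function(diag) {
    structure(list(value = NA_integer_, found = FALSE, method = method,
                   diagnostics = diag), class = "completeness_threshold")
  }
  if (stats::sd(z) == 0) return(not_found(list(reason = "constant counts")))

  if (method == "valley") {
    bw <- stats::sd(z) * length(z)^(-1 / 5)  # Scott's rule, 1-D
    den <- stats::density(z, bw = bw, n = n_grid)
    y <- den$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1L
    # only count modes with non-trivial height
    is_max <- is_max[y[is_max] >= 0.05 * max(y)]
    if (length(is_max) < 2L) {
      return(not_found(list(reason = "unimodal density", bw = bw)))
    }
    top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
    between <- seq(top2[1], top2[2])
    vi <- between[which.min(y[between])]
    # the dip must be a genuine valley, not a smoothing wiggle
    if (vi == top2[1] || vi == top2[2] ||
        y[vi] > 0.9 * min(y[top2])) {
      return(not_found(list(reason = "no interior minimum", bw = bw)))
    }
    value <- max(1L, as.integer(round(10^den$x[vi] - 1)))
    diag <- list(bw = bw, modes = 10^den$x[top2] - 1,
                 valley_log10 = den$x[vi], density = den)
  } else {
    tab <- table(z)
    x <- as.numeric(names(tab))
    yf <- log10(as.numeric(tab))
    if (length(x) < 5L) return(not_found(list(reason = "too few distinct counts")))
    # grid search over interior breakpoints of a continuous 2-segment fit
    cand <- x[seq(3L, length(x) - 2L)]
    sse <- vapply(cand, function(b) {
      h <- pmax(x - b, 0)
      sum(stats::lm.fit(cbind(1, x, h), yf)$residuals^2)
    }, 0)
    b <- cand[which.min(sse)]
    value <- max(1L, as.integer(round(10^b - 1)))
    h <- pmax(x - b, 0)
    fit <- stats::lm.fit(cbind(1, x, h), yf)
    diag <- list(breakpoint_log10 = b,
                 slopes = c(left = unname(fit$coefficients[2]),
                            right = unname(fit$coefficients[2] + fit$coefficients[3])),
                 sse = min(sse))
  }
  structure(list(value = value, found = TRUE, method = method,
                 diagnostics = diag), class = "completeness_threshold")
}

#' @export
print.completeness_threshold <- function(x, ...) {
  if (x$found) {
    cat(sprintf("completeness threshold: %d synapses (%s method)\n",
                x$value, x$method))
  } else {
    cat(sprintf("no completeness threshold found (%s): %s\n", x$method,
                x$diagnostics$reason))
  }
  invisible(x)
}

#' Compute per-neuron region synapse fractions
#'
#' A neuron's pre-synaptic sites are the table rows where it is the
#' pre-synaptic partner, and symmetrically for post. Fractions are in-region
#' site count over total site count per polarity; the combined fraction pools
#' both polarities. Neurons lacking one polarity get `NA` for that fraction
#' (flagged); neurons with zero total sites are excluded with a warning.
#'
#' @param sites a `synapse_table`.
#' @param region region label, or character vector of labels whose union
#'   counts as in-region (e.g. [sp_region()]).
#' @param neuron_ids neurons to evaluate; defaults to every id in `sites`.
#' @return data.frame of class `region_fractions` with columns `neuron_id`,
#'   `n_pre`, `n_post`, `pre_frac`, `post_frac`, `combined_frac`.
#' @export
compute_region_fractions <- function(sites, region, neuron_ids = NULL) {
  if (is.null(neuron_ids)) {
    neuron_ids <- sort(unique(c(sites$pre_id, sites$post_id)))
  }
  inreg <- sites$region %in% region
  pre_tot <- table(factor(sites$pre_id, levels = neuron_ids))
  post_tot <- table(factor(sites$post_id, levels = neuron_ids))
  pre_in <- table(factor(sites$pre_id[inreg], levels = neuron_ids))
  post_in <- table(factor(sites$post_id[inreg], levels = neuron_ids))
  out <- data.frame(
    neuron_id = neuron_ids,
    n_pre = as.integer(pre_tot), n_post = as.integer(post_tot),
    stringsAsFactors = FALSE)
  out$pre_frac <- ifelse(out$n_pre > 0, as.integer(pre_in) / out$n_pre, NA_real_)
  out$post_frac <- ifelse(out$n_post > 0, as.integer(post_in) / out$n_post, NA_real_)
  tot <- out$n_pre + out$n_post
  out$combined_frac <- ifelse(tot > 0,
                              (as.integer(pre_in) + as.integer(post_in)) / tot,
                              NA_real_)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " neuron(s) with zero synaptic sites excluded")
    out <- out[tot > 0, , drop = FALSE]
  }
  class(out) <- c("region_fractions", "data.frame")
  out
}

#' Select region-intrinsic neurons
#'
#' A neuron is intrinsic when strictly more than `threshold` of its synaptic
#' sites lie in the focal region. The `"combined"` rule tests the pooled
#' fraction; the `"both_polarity"` rule requires both the pre- and the
#' post-fraction to clear the threshold (matching the high-pre x high-post
#' corner of the fraction scatter). The boundary is excluded: exactly 85%
#' does not qualify.
#'
#' @param fractions a `region_fractions` data.frame.
#' @param rule `"both_polarity"` (default) or `"combined"`.
#' @param threshold fraction in (0, 1); default 0.85.
#' @return character vector of selected neuron ids, with attributes `rule`
#'   and `threshold`.
#' @export
select_intrinsic <- function(fractions, rule = c("both_polarity", "combined"),
                             threshold = 0.85) {
  rule <- match.arg(rule)
  stopifnot(threshold > 0, threshold < 1)
  keep <- if (rule == "combined") {
    !is.na(fractions$combined_frac) & fractions$combined_frac > threshold
  } else {
    !is.na(fractions$pre_frac) & !is.na(fractions$post_frac) &
      fractions$pre_frac > threshold & fractions$post_frac > threshold
  }
  structure(fractions$neuron_id[keep], rule = rule, threshold = threshold)
}

#' Complete the intrinsic set by cell type
#'
#' The completeness threshold truncates the pre-synaptic count histogram of
#' the selected population, so neurons that (a) share a cell type with at
#' least one selected neuron, (b) themselves pass the intrinsic fraction
#' rule, and (c) fall below `min_presyn` pre-synaptic sites are added back.
#' Neurons with an empty cell type are never added. A user-supplied exclusion
#' list of reported cell types is removed from the final set.
#'
#' @param selected character vector of selected neuron ids.
#' @param metadata neuron metadata (columns `id`, `cell_type`, `n_pre`).
#' @param fractions `region_fractions` covering candidate neurons.
#' @param min_presyn pre-synaptic site threshold (default 75).
#' @param rule,threshold intrinsic rule applied to candidates, as in
#'   [select_intrinsic()].
#' @param exclude_types cell types to drop from the final set.
#' @return augmented character vector of neuron ids.
#' @export
complete_types <- function(selected, metadata, fractions, min_presyn = 75L,
                           rule = c("both_polarity", "combined"),
                           threshold = 0.85, exclude_types = character()) {
  rule <- match.arg(rule)
  if (length(selected) == 0L) return(character())
  sel_types <- unique(metadata$cell_type[metadata$id %in% selected])
  sel_types <- setdiff(sel_types, "")
  cand <- metadata$id[metadata$cell_type %in% sel_types &
                        !(metadata$id %in% selected) &
                        metadata$n_pre < min_presyn]
  if (length(cand) > 0L) {
    fr <- fractions[fractions$neuron_id %in% cand, , drop = FALSE]
    cand <- select_intrinsic(fr, rule = rule, threshold = threshold)
  }
  out <- union(selected, cand)
  if (length(exclude_types) > 0L) {
    unknown <- setdiff(exclude_types, metadata$cell_type)
    if (length(unknown) > 0L) {
      warning("exclusion list names unknown cell type(s): ",
              paste(unknown, collapse = ", "))
    }
    drop_ids <- metadata$id[metadata$cell_type %in% exclude_types]
    out <- setdiff(out, drop_ids)
  }
  out
}

#' Fit the binned pre/post fraction curve
#'
#' Bins neurons by pre-synaptic in-region fraction into half-open intervals
#' of width `bin_size`, takes the mean post-synaptic fraction per bin, and
#' fits a degree-2 polynomial by ordinary least squares.
#'
#' @param fractions a `region_fractions` data.frame.
#' @param bin_size bin width in fraction units (default 0.05).
#' @return list of class `fraction_curve`: `coefficients` (`a`, `b`, `c` of
#'   `y = a x^2 + b x + c`), `r_squared`, `bin_size`, `bins` (the binned
#'   points), `zero_variance` flag.
#' @export
fit_fraction_curve <- function(fractions, bin_size = 0.05) {
  ok <- !is.na(fractions$pre_frac) & !is.na(fractions$post_frac)
  x0 <- fractions$pre_frac[ok]
  y0 <- fractions$post_frac[ok]
  bin <- floor(x0 / bin_size)  # [k*b, (k+1)*b)
  bx <- tapply(x0, bin, mean)
  by <- tapply(y0, bin, mean)
  if (length(bx) < 3L) stop("need at least 3 non-empty bins")
  x <- as.numeric(bx)
  y <- as.numeric(by)
  fit <- stats::lm(y ~ I(x^2) + x)
  co <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  zero_var <- ss_tot == 0
  r2 <- if (zero_var) 1 else 1 - ss_res / ss_tot
  structure(list(
    coefficients = c(a = unname(co["I(x^2)"]), b = unname(co["x"]),
                     c = unname(co["(Intercept)"])),
    r_squared = r2, bin_size = bin_size,
    bins = data.frame(x = x, y = y),
    zero_variance = zero_var), class = "fraction_curve")
}

#' @export
print.fraction_curve <- function(x, ...) {
  cat(sprintf("y = %.3fx^2 + %.3fx + %.3f, R^2 = %.3f (%d bins of %.0f%%)\n",
              x$coefficients["a"], x$coefficients["b"], x$coefficients["c"],
              x$r_squared, nrow(x$bins), 100 * x$bin_size))
  invisible(x)
}
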