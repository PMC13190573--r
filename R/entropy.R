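# Shannon-entropy diversity analysis of hub connectivity, with three null
# models: labeled-line (all weight on one partner, H = 0), mixed (uniform
# weight over all partners, H = log2 N), and a shuffled null that permutes
# partner labels while preserving each hub's weight multiset.

#' Shannon entropy of a synaptic weight vector
#'
#' Normalises non-negative weights to proportions and returns
#' `H = -sum(p * log2(p))` in bits, with the convention `0 * log2(0) = 0`.
#' Bounded between 0 (all weight on one partner) and `log2(N)` (uniform over
#' `N` partners).
#'
#' @param weights non-negative numeric vector with at least one positive
#'   entry.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(weights) {
  stopifnot(all(weights >= 0))
  s <- sum(weights)
  if (s <= 0) stop("all-zero weight vector has no defined entropy")
  p <- weights[weights > 0] / s
  -sum(p * log2(p))
}

#' Per-hub entropy report for a connectivity graph
#'
#' For each hub, collects the synaptic weights to its upstream partners
#' (`direction = "input"`) or downstream partners (`"output"`) and computes
#' the Shannon entropy, partner count, and entropy deficit
#' `H - log2(N)` (non-positive; 0 iff the weights are uniform).
#'
#' @param graph a `conn_graph`.
#' @param hubs character vector of hub neuron ids.
#' @param direction `"input"` or `"output"`.
#' @return data.frame `hub`, `H`, `N`, `deficit`, `direction`; hubs with no
#'   partners on the requested side are omitted.
#' @export
hub_entropies <- function(graph, hubs, direction = c("input", "output")) {
  direction <- match.arg(direction)
  ed <- graph$edges
  rows <- lapply(hubs, function(h) {
    w <- if (direction == "input") ed$weight[ed$post == h] else ed$weight[ed$pre == h]
    if (length(w) == 0L) return(NULL)
    data.frame(hub = h, H = shannon_entropy(w), N = length(w),
               deficit = shannon_entropy(w) - log2(length(w)),
               direction = direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

null_result <- function(kind, statistic, p_value, n_replicates = NA_integer_,
                        mu_null = NA_real_, sigma_null = NA_real_,
                        flag = NA_character_) {
  structure(list(null_kind = kind, statistic = statistic, p_value = p_value,
                 n_replicates = n_replicates, mu_null = mu_null,
                 sigma_null = sigma_null, flag = flag),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("%s null: statistic = %.4g, p = %.4g%s\n", x$null_kind,
              x$statistic, x$p_value,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

one_sample_t <- function(values, kind) {
  stopifnot(length(values) >= 2L)
  if (stats::sd(values) == 0) {
    if (mean(values) == 0) {
      return(null_result(kind, 0, 1, flag = "all_zero"))
    }
    return(null_result(kind, sign(mean(values)) * Inf, 0,
                       flag = "zero_variance"))
  }
  tt <- stats::t.test(values, mu = 0)
  null_result(kind, unname(tt$statistic), tt$p.value)
}

#' Test the labeled-line null on observed hub entropies
#'
#' Under a labeled-line architecture every hub is dominated by a single
#' partner and its entropy is 0; the test is a two-sided one-sample t-test of
#' observed entropies against 0. Degenerate inputs are flagged: all-zero
#' entropies give `t = 0, p = 1` by convention (null retained), constant
#' nonzero entropies give an infinite statistic with p = 0.
#'
#' @param entropies per-hub entropy values (from [hub_entropies()]).
#' @return a `null_test_result`.
#' @export
labeled_line_test <- function(entropies) {
  one_sample_t(entropies, "labeled_line")
}

#' Test the mixed (all-to-all uniform) null on entropy deficits
#'
#' Under the mixed null each hub spreads weight uniformly over its partners,
#' so the entropy deficit `H - log2(N)` is 0; the test is a one-sample
#' t-test of deficits against 0, with the same degenerate conventions as
#' [labeled_line_test()].
#'
#' @param deficits per-hub entropy deficits (from [hub_entropies()]).
#' @return a `null_test_result`.
#' @export
mixed_model_test <- function(deficits) {
  one_sample_t(deficits, "mixed")
}

# one replicate of the shuffled null: globally permute the partner-label pool
# across all hub-incident connections; each hub keeps its own weight multiset
# but collisions merge (same partner drawn twice pools the weight), which is
# what distinguishes specific wiring from a degree-matched random assignment.
# hub/partner are integer codes; fully vectorised via rowsum.
shuffle_mean_entropy <- function(hub_code, partner_code, weight, n_partner) {
  key <- hub_code * (n_partner + 1) + sample(partner_code)
  merged <- rowsum(weight, key)[, 1L]
  hub_m <- floor(as.numeric(names(merged)) / (n_partner + 1))
  tot <- rowsum(merged, hub_m)[, 1L]
  p <- merged / tot[match(hub_m, as.numeric(names(tot)))]
  h_per_hub <- rowsum(-p * log2(p), hub_m)[, 1L]
  mean(h_per_hub)
}

#' Shuffled-null entropy test
#'
#' Randomly reassigns partner labels across all hub connections while
#' preserving each hub's number of connections and weight multiset, repeats
#' `n_replicates` times, and compares the observed mean hub entropy to the
#' replicate distribution via `Z = (H_obs - mu) / sigma` with a two-sided
#' normal p-value.
#'
#' @param graph a `conn_graph`.
#' @param hubs hub neuron ids present in the graph.
#' @param direction `"input"` or `"output"`.
#' @param n_replicates number of shuffles (default 100).
#' @param seed integer seed.
#' @return a `null_test_result`; if the replicate standard deviation is 0
#'   the Z is undefined and flagged.
#' @export
shuffled_null_test <- function(graph, hubs, direction = c("input", "output"),
                               n_replicates = 100L, seed = 1L) {
  direction <- match.arg(direction)
  ed <- graph$edges
  keep <- if (direction == "input") ed$post %in% hubs else ed$pre %in% hubs
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed) == 0L) stop("no hub-incident connections on the requested side")
  hub_of <- if (direction == "input") ed$post else ed$pre
  partner_of <- if (direction == "input") ed$pre else ed$post
  h_obs <- mean(vapply(split(ed$weight, hub_of), shannon_entropy, 0))
  hub_code <- as.integer(factor(hub_of))
  partner_code <- as.integer(factor(partner_of))
  n_partner <- max(partner_code)
  reps <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      shuffle_mean_entropy(hub_code, partner_code, ed$weight, n_partner)
    }, 0)
  })
  mu <- mean(reps)
  sg <- stats::sd(reps)
  if (sg < 1e-12) {
    return(null_result("shuffled", NA_real_, NA_real_, n_replicates,
                       mu, sg, flag = "undefined_z"))
  }
  z <- (h_obs - mu) / sg
  null_result("shuffled", z, 2 * stats::pnorm(-abs(z)), n_replicates, mu, sg)
}

#' Run the three-null entropy battery and classify the architecture
#'
#' Applies the labeled-line, mixed, and shuffled nulls to the hub entropies
#' of a connectivity graph and classifies the generating architecture by the
#' rejection signature:
#' \itemize{
#'   \item labeled-line null not rejected (all entropies at 0) ->
#'     `"labeled_line"`;
#'   \item labeled-line rejected and shuffled null rejected (partner labels
#'     carry structure a degree-matched random assignment reproduces
#'     differently) -> `"mixed"`;
#'   \item labeled-line rejected but shuffled null not rejected (dedicated,
#'     non-colliding partner sets make the shuffle distribution degenerate)
#'     -> `"convergence_divergence"`.
#' }
#' A flagged/undefined shuffled Z counts as not rejected.
#'
#' @param graph a `conn_graph`.
#' @param hubs hub neuron ids.
#' @param direction side of the hubs to test.
#' @param alpha significance level (default 0.01).
#' @param n_replicates shuffled-null replicates.
#' @param seed integer seed.
#' @return list of class `architecture_battery`: `entropies`, `labeled_line`,
#'   `mixed`, `shuffled`, `rejected` (named logical), `classified`.
#' @export
architecture_battery <- function(graph, hubs, direction = c("input", "output"),
                                 alpha = 0.01, n_replicates = 100L, seed = 1L) {
  direction <- match.arg(direction)
  ent <- hub_entropies(graph, hubs, direction)
  if (is.null(ent) || nrow(ent) < 2L) stop("need >= 2 hubs with partners")
  ll <- labeled_line_test(ent$H)
  mx <- mixed_model_test(ent$deficit)
  sh <- shuffled_null_test(graph, hubs, direction, n_replicates, seed)
  rejected <- c(
    labeled_line = is.finite(ll$p_value) && ll$p_value < alpha,
    mixed = is.finite(mx$p_value) && mx$p_value < alpha,
    shuffled = !is.na(sh$p_value) && sh$p_value < alpha)
  classified <- if (!rejected[["labeled_line"]]) {
    "labeled_line"
  } else if (rejected[["shuffled"]]) {
    "mixed"
  } else {
    "convergence_divergence"
  }
  structure(list(entropies = ent, labeled_line = ll, mixed = mx, shuffled = sh,
                 rejected = rejected, classified = classified, alpha = alpha),
            class = "architecture_battery")
}

#' @export
print.architecture_battery <- function(x, ...) {
  cat(sprintf("architecture battery (%d hubs, alpha = %g)\n",
              nrow(x$entropies), x$alpha))
  for (k in c("labeled_line", "mixed", "shuffled")) print(x[[k]])
  cat("rejected:", paste(names(x$rejected)[x$rejected], collapse = ", "),
      "\nclassified as:", x$classified, "\n")
  invisible(x)
}
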