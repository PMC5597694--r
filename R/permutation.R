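#' Individual-resampling permutation test for diversity differences
#'
#' Tests whether two taxa differ in nucleotide diversity. All individuals
#' of the two groups are pooled and repeatedly re-partitioned at random
#' (without replacement) into two groups of the original sizes; the
#' exchangeable unit is the individual, whose two allele sequences always
#' travel together, accounting for the non-independence of alleles within
#' a genotype. Each permutation recomputes pi for both groups and the
#' absolute difference; the p value is the proportion of permutations with
#' a difference at least as large as the observed one, the observed
#' arrangement itself counted as one permutation (so p >= 1/N).
#'
#' @param g1,g2 \code{seq_matrix} objects for the two groups (see
#'   \code{\link{build_matrix}}); individual ids must not overlap
#' @param n_perm total number of permutations N, observed included
#'   (default 10000)
#' @param seed RNG seed for reproducibility
#' @return object of class \code{permutation_result}: \code{pi1},
#'   \code{pi2}, \code{observed_delta}, \code{n_perm}, \code{p},
#'   \code{n1}, \code{n2}
#' @export
perm_test <- function(g1, g2, n_perm = 10000L, seed = NULL) {
  pooled <- pool_groups(g1, g2)
  if (pooled$n1 < 2L || pooled$n2 < 2L)
    stop("each group needs at least 2 individuals")
  obs <- pooled_delta(pooled, seq_len(pooled$n1))
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L)
  n <- pooled$n1 + pooled$n2
  deltas <- with_seed(seed, vapply(seq_len(n_perm - 1L), function(b) {
    pooled_delta(pooled, sample.int(n, pooled$n1))$delta
  }, numeric(1)))
  hits <- 1L + sum(deltas >= obs$delta - 1e-12)
  structure(list(pi1 = obs$pi1, pi2 = obs$pi2, observed_delta = obs$delta,
                 n_perm = n_perm, p = hits / n_perm,
                 n1 = pooled$n1, n2 = pooled$n2),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: pi1 = %.6f, pi2 = %.6f, |delta| = %.6f\n  N = %d permutations, p = %.4g (n1 = %d, n2 = %d individuals)\n",
    x$pi1, x$pi2, x$observed_delta, x$n_perm, x$p, x$n1, x$n2))
  invisible(x)
}

# precompute pooled pairwise-pi matrix and per-individual row indices
pool_groups <- function(g1, g2) {
  stopifnot(inherits(g1, "seq_matrix"), inherits(g2, "seq_matrix"))
  if (length(intersect(unique(g1$individual), unique(g2$individual))))
    stop("groups share individual ids; they must be disjoint")
  seqs <- c(g1$seq, g2$seq)
  ind <- c(g1$individual, g2$individual)
  inds <- unique(ind)
  rows_of <- split(seq_along(ind), factor(ind, levels = inds))
  P <- pairwise_pi(seqs)$P
  list(P = P, rows_of = rows_of,
       n1 = length(unique(g1$individual)), n2 = length(unique(g2$individual)))
}

# |pi(group of individuals idx) - pi(complement)|
pooled_delta <- function(pooled, idx1) {
  n <- length(pooled$rows_of)
  idx2 <- setdiff(seq_len(n), idx1)
  r1 <- unlist(pooled$rows_of[idx1], use.names = FALSE)
  r2 <- unlist(pooled$rows_of[idx2], use.names = FALSE)
  pi1 <- subset_pi(pooled$P, r1)
  pi2 <- subset_pi(pooled$P, r2)
  list(pi1 = pi1, pi2 = pi2, delta = abs(pi1 - pi2))
}

#' Exact permutation p value by exhaustive enumeration
#'
#' Enumerates every partition of the pooled individuals into groups of the
#' original sizes (C(n1+n2, n1) assignments, observed included) and
#' returns the exact proportion with an absolute diversity difference at
#' least the observed one. Serves as the small-sample oracle for
#' \code{\link{perm_test}}.
#'
#' @inheritParams perm_test
#' @param max_partitions refuse above this many partitions (default 1e5)
#' @return list: \code{p}, \code{observed_delta}, \code{n_partitions}
#' @export
exhaustive_test <- function(g1, g2, max_partitions = 1e5) {
  pooled <- pool_groups(g1, g2)
  n <- pooled$n1 + pooled$n2
  n_part <- choose(n, pooled$n1)
  if (n_part > max_partitions)
    stop(sprintf("C(%d,%d) = %.0f partitions exceeds %g; use perm_test (Monte Carlo)",
                 n, pooled$n1, n_part, max_partitions))
  obs <- pooled_delta(pooled, seq_len(pooled$n1))
  sets <- utils::combn(n, pooled$n1)
  deltas <- apply(sets, 2L, function(idx) pooled_delta(pooled, idx)$delta)
  list(p = mean(deltas >= obs$delta - 1e-12),
       observed_delta = obs$delta, n_partitions = as.integer(n_part))
}

#' Bonferroni correction for a family of permutation tests
#'
#' Divides the family-wise level alpha by the number of tests and flags
#' significance with a less-than-or-equal comparison, so a p value exactly
#' at the adjusted threshold is significant.
#'
#' @param p numeric vector of p values (or list of
#'   \code{permutation_result}s)
#' @param alpha family-wise significance level (default 0.05)
#' @param n_tests number of tests in the family (default:
#'   \code{length(p)})
#' @return data.frame: p, alpha_adjusted, significant
#' @export
bonferroni <- function(p, alpha = 0.05, n_tests = NULL) {
  if (is.list(p)) p <- vapply(p, function(r) r$p, numeric(1))
  stopifnot(is.numeric(p), alpha > 0, alpha < 1)
  if (is.null(n_tests)) n_tests <- length(p)
  stopifnot(n_tests >= 1, n_tests >= length(p) || length(p) == 0)
  thr <- alpha / n_tests
  data.frame(p = p, alpha_adjusted = thr,
             significant = p <= thr * (1 + 1e-12))
}

#' Pairwise permutation tests across taxon scopes and loci
#'
#' Runs \code{\link{perm_test}} for every requested (locus, taxon-pair)
#' combination over the all-exons selection, applies a Bonferroni
#' correction across the whole family, and returns a tidy table plus a
#' run manifest (seeds per test, derived deterministically from the base
#' seed and the test id so adding tests never perturbs earlier ones).
#'
#' @param gt a \code{genotype_table}
#' @param seqs named aligned allele sequences
#' @param comparisons data.frame with columns \code{locus1}, \code{locus2}
#'   (locus names as typed in each taxon), \code{taxa1}, \code{taxa2}
#'   (taxon labels); loci must share one gene model/alignment
#' @param models named list of \code{gene_model}s keyed by locus name
#' @param n_perm permutations per test
#' @param alpha family-wise level
#' @param n_tests Bonferroni denominator (default: number of comparisons)
#' @param seed base seed
#' @param exclude optional individuals to drop
#' @return list: \code{results} (data.frame), \code{manifest}
#' @export
permutation_scan <- function(gt, seqs, comparisons, models,
                             n_perm = 10000L, alpha = 0.05, n_tests = NULL,
                             seed = 1L, exclude = NULL) {
  stopifnot(is.data.frame(comparisons),
            all(c("locus1", "locus2", "taxa1", "taxa2") %in% names(comparisons)))
  res <- list(); seeds <- integer(0)
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, ]
    id <- sprintf("%s~%s|%s~%s", cmp$locus1, cmp$taxa1, cmp$locus2, cmp$taxa2)
    s <- derive_seed(seed, id)
    g1 <- build_matrix(gt, seqs, cmp$locus1, models[[cmp$locus1]],
                       taxa = cmp$taxa1, exclude = exclude)
    g2 <- build_matrix(gt, seqs, cmp$locus2, models[[cmp$locus2]],
                       taxa = cmp$taxa2, exclude = exclude)
    pt <- perm_test(g1, g2, n_perm = n_perm, seed = s)
    seeds[id] <- s
    res[[i]] <- data.frame(test = id, locus = cmp$locus1,
                           taxa1 = cmp$taxa1, taxa2 = cmp$taxa2,
                           pi1 = pt$pi1, pi2 = pt$pi2,
                           delta = pt$observed_delta, n_perm = pt$n_perm,
                           p = pt$p, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  nt <- if (is.null(n_tests)) nrow(tab) else n_tests
  bf <- bonferroni(tab$p, alpha = alpha, n_tests = nt)
  tab$alpha_adjusted <- bf$alpha_adjusted
  tab$significant <- bf$significant
  list(results = tab,
       manifest = list(seed = seed, seeds = as.list(seeds),
                       n_perm = n_perm, alpha = alpha, n_tests = nt))
}
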