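#' Nucleotide diversity over diploid genotype sets
#'
#' Nucleotide diversity (pi) is the mean per-site nucleotide difference
#' between two sequences drawn from the sample. For n diploid individuals
#' the sample holds 2n sequences (both alleles of every individual,
#' homozygotes duplicated) and pi averages over all C(2n,2) sequence
#' pairs; a sequence is never compared against itself. Sites are compared
#' under pairwise deletion: for each pair only columns where both
#' sequences carry an unambiguous A/C/G/T base contribute.
#'
#' @name diversity
NULL

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer code matrix (m x L): 1-4 for ACGT, 0 for gap/ambiguity
encode_bases <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences differ in length: ", paste(range(nchar(seqs)), collapse = " vs "))
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  codes <- BASE_CODES[chars]
  codes[is.na(codes)] <- 0L
  matrix(codes, nrow = length(seqs), ncol = L)
}

#' Per-pair nucleotide differences with pairwise deletion
#'
#' @param seqs character vector of equal-length (aligned) sequences
#' @return list with symmetric matrices \code{P} (per-pair differences per
#'   compared site; NaN where a pair shares no comparable site), \code{D}
#'   (mismatch counts) and \code{L} (compared sites per pair)
#' @export
pairwise_pi <- function(seqs) {
  X <- encode_bases(seqs)
  V <- (X > 0L) * 1
  Lmat <- tcrossprod(V)
  match <- matrix(0, nrow(X), nrow(X))
  for (b in seq_len(4L)) {
    Bb <- (X == b) * 1
    match <- match + tcrossprod(Bb)
  }
  D <- Lmat - match
  P <- D / Lmat                       # NaN where Lmat == 0
  diag(P) <- 0
  list(P = P, D = D, L = Lmat)
}

#' Build a region-restricted sequence matrix from genotypes
#'
#' Selects individuals by taxon, resolves their called alleles against the
#' aligned sequence set, restricts to the requested gene-model regions
#' (slices concatenated in model order) and returns two rows per
#' individual, homozygotes duplicated.
#'
#' @param gt a \code{genotype_table}
#' @param seqs named character vector (or \code{Biostrings::DNAStringSet})
#'   of aligned full-length allele sequences, names matching the genotype
#'   calls
#' @param locus locus to extract
#' @param model \code{gene_model} for the locus
#' @param regions character vector of segment labels to keep (default: all
#'   exons); \code{"all"} keeps the whole alignment
#' @param taxa optional taxon filter
#' @param exclude optional individual ids to drop (e.g. to match sample
#'   sizes between groups)
#' @return object of class \code{seq_matrix}: list with \code{seq}
#'   (character vector, 2 per individual), \code{individual}, \code{taxon},
#'   \code{locus}, \code{regions}
#' @export
build_matrix <- function(gt, seqs, locus, model, regions = NULL,
                         taxa = NULL, exclude = NULL) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  sub <- gt[gt$locus == locus & !gt$absent & !is.na(gt$allele1), , drop = FALSE]
  if (!is.null(taxa)) sub <- sub[sub$taxon %in% taxa, , drop = FALSE]
  if (!is.null(exclude)) sub <- sub[!sub$individual %in% exclude, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no individuals selected for locus ", locus)
  calls <- genotype_calls(sub)
  missing <- setdiff(unique(calls$allele), names(seqs))
  if (length(missing)) {
    who <- calls$individual[calls$allele == missing[1]][1]
    stop(sprintf("no aligned sequence for allele '%s' (called in individual '%s')",
                 missing[1], who))
  }
  full <- unname(seqs[calls$allele])
  if (any(nchar(full) != model_length(model)))
    stop("aligned sequences do not match the gene model length")
  if (is.null(regions)) {
    regions <- model$segments$label[model$segments$kind == "exon"]
  } else if (identical(regions, "all")) {
    regions <- model$segments$label
  }
  seg <- model$segments
  if (!all(regions %in% seg$label))
    stop("unknown region label(s): ",
         paste(setdiff(regions, seg$label), collapse = ", "))
  keep <- seg[seg$label %in% regions, , drop = FALSE]   # model order
  cut <- vapply(full, function(s)
    paste(substring(s, keep$start, keep$end), collapse = ""), character(1),
    USE.NAMES = FALSE)
  structure(list(seq = cut, individual = calls$individual,
                 taxon = calls$taxon, locus = locus,
                 regions = keep$label),
            class = "seq_matrix")
}

as_seqs <- function(x) {
  if (inherits(x, "seq_matrix")) x$seq else x
}

#' Nucleotide diversity (pi) with standard error
#'
#' pi is the mean over all sequence pairs of per-pair per-site mismatches
#' (pairwise deletion of gap/ambiguity columns). The default standard
#' error is the Nei-style sampling variance of pi (stochastic and sampling
#' terms); alternatively a bootstrap over individuals is available (the
#' individual, i.e. both its alleles, is the resampling unit).
#'
#' @param x a \code{seq_matrix} from \code{\link{build_matrix}}, or a
#'   character vector of aligned sequences
#' @param se_method "nei" or "bootstrap"
#' @param n_boot bootstrap resamples (bootstrap SE only)
#' @param seed RNG seed (bootstrap SE only)
#' @return list of class \code{diversity_estimate}: \code{pi}, \code{se},
#'   \code{m} (sequences), \code{L_effective} (mean compared sites per
#'   pair), \code{n_pairs}
#' @export
nucleotide_diversity <- function(x, se_method = c("nei", "bootstrap"),
                                 n_boot = 1000L, seed = NULL) {
  se_method <- match.arg(se_method)
  seqs <- as_seqs(x)
  m <- length(seqs)
  if (m < 2L) stop("need at least 2 sequences, got ", m)
  pw <- pairwise_pi(seqs)
  ut <- upper.tri(pw$P)
  vals <- pw$P[ut]
  Ls <- pw$L[ut]
  bad <- Ls == 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) share no comparable site; excluded")
    vals <- vals[!bad]; Ls <- Ls[!bad]
  }
  if (!length(vals)) stop("no comparable pairs")
  pi_hat <- mean(vals)
  L_eff <- mean(Ls)
  se <- switch(se_method,
    nei = se_nei(pi_hat, m, L_eff),
    bootstrap = se_bootstrap_individuals(pw$P, x, n_boot = n_boot, seed = seed))
  structure(list(pi = pi_hat, se = se, m = m, L_effective = L_eff,
                 n_pairs = length(vals)),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("pi = %.6f (SE %.6f), m = %d sequences, %.1f sites/pair\n",
              x$pi, x$se, x$m, x$L_effective))
  invisible(x)
}

# Nei (1987)-style sampling variance of pi for n sequences and L sites:
# V = (n+1)/(3(n-1)L) * pi + 2(n^2+n+3)/(9n(n-1)) * pi^2
se_nei <- function(pi_hat, n, L) {
  if (pi_hat == 0) return(0)
  v <- (n + 1) / (3 * (n - 1) * L) * pi_hat +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  sqrt(v)
}

# bootstrap over individuals: rows travel in per-individual pairs
se_bootstrap_individuals <- function(P, x, n_boot = 1000L, seed = NULL) {
  if (!inherits(x, "seq_matrix"))
    stop("bootstrap SE needs a seq_matrix (individual pairing)")
  inds <- unique(x$individual)
  rows_of <- split(seq_along(x$individual), x$individual)[inds]
  n <- length(inds)
  stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(n, n, replace = TRUE)
    rows <- unlist(rows_of[pick], use.names = FALSE)
    subset_pi(P, rows)
  }, numeric(1)))
  stats::sd(stats)
}

# mean of P over unordered pairs of (possibly repeated) row slots
subset_pi <- function(P, rows) {
  k <- length(rows)
  S <- P[rows, rows, drop = FALSE]
  ok <- !is.nan(S)
  n_pairs <- (sum(ok) - k) / 2      # diagonal is 0, never NaN
  sum(S[ok]) / 2 / n_pairs
}

#' Per-region diversity profile of a locus
#'
#' One diversity estimate per gene-model segment, in model order (E1, I1,
#' E2, ...), mirroring per-exon/per-intron diversity panels.
#'
#' @inheritParams build_matrix
#' @param se_method passed to \code{\link{nucleotide_diversity}}
#' @return data.frame: region, kind, m, pi, se, L_effective
#' @export
region_profile <- function(gt, seqs, locus, model, taxa = NULL,
                           exclude = NULL, se_method = "nei") {
  seg <- model$segments
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    sm <- build_matrix(gt, seqs, locus, model, regions = seg$label[i],
                       taxa = taxa, exclude = exclude)
    est <- nucleotide_diversity(sm, se_method = se_method)
    data.frame(region = seg$label[i], kind = seg$kind[i], m = est$m,
               pi = est$pi, se = est$se, L_effective = est$L_effective,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tidy diversity summary across loci and taxon scopes
#'
#' Computes pi over the all-exons selection and optionally the full
#' per-region profile for each locus and named taxon scope.
#'
#' @param gt a \code{genotype_table}
#' @param seqs aligned allele sequences (named)
#' @param models named list of \code{gene_model}s, names = locus names in
#'   \code{gt}
#' @param scopes named list of taxon filters (NULL = all taxa)
#' @param per_region also emit one row per exon/intron? default TRUE
#' @param exclude optional individuals to drop
#' @return data.frame: scope, locus, region, m, pi, se, L_effective
#' @export
diversity_scan <- function(gt, seqs, models, scopes, per_region = TRUE,
                           exclude = NULL) {
  out <- list()
  for (sc in names(scopes)) for (locus in names(models)) {
    model <- models[[locus]]
    sm <- tryCatch(build_matrix(gt, seqs, locus, model, taxa = scopes[[sc]],
                                exclude = exclude),
                   error = function(e) NULL)
    if (is.null(sm)) next
    est <- nucleotide_diversity(sm)
    out[[length(out) + 1L]] <- data.frame(
      scope = sc, locus = locus, region = "all_exons", m = est$m,
      pi = est$pi, se = est$se, L_effective = est$L_effective,
      stringsAsFactors = FALSE)
    if (per_region) {
      prof <- region_profile(gt, seqs, locus, model, taxa = scopes[[sc]],
                             exclude = exclude)
      out[[length(out) + 1L]] <- cbind(scope = sc, locus = locus,
                                       prof[, c("region", "m", "pi", "se",
                                                "L_effective")])
    }
  }
  do.call(rbind, out)
}
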