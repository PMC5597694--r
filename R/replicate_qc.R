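#' Replicate reconciliation and spurious-deletion detection
#'
#' Long-amplicon genotyping is run in duplicate PCR replicates per
#' individual and locus. Usually both replicates call identical allele
#' sets; the characteristic failure mode is a consensus-calling artifact
#' in which two very similar true alleles collapse into one sequence that
#' carries a frameshifting deletion and a premature stop codon. These
#' rules re-implement that adjudication: a replicate pair is resolved in
#' favour of the two-allele call only when the solitary allele shows the
#' full three-part deletion signature.
#'
#' @name replicate_qc
NULL

#' Construct a replicate call set
#'
#' @param individual individual id
#' @param locus locus id
#' @param replicate replicate number (1 or 2)
#' @param alleles named character vector of 1-2 aligned allele sequences
#' @param read_support optional integer read counts per allele
#' @return list of class \code{replicate_call_set}
#' @export
replicate_call_set <- function(individual, locus, replicate, alleles,
                               read_support = NULL) {
  stopifnot(replicate %in% 1:2, length(alleles) %in% 1:2,
            is.character(alleles))
  if (!is.null(read_support))
    stopifnot(length(read_support) == length(alleles))
  structure(list(individual = individual, locus = locus,
                 replicate = as.integer(replicate), alleles = alleles,
                 read_support = read_support),
            class = "replicate_call_set")
}

#' Spurious-deletion signature check
#'
#' A solitary allele is a spurious collapse of two true alleles iff
#' \enumerate{
#'   \item it carries a deletion (gap column where both pair members have
#'     a base) inside an exon,
#'   \item at least one such deletion column coincides with a column where
#'     the two pair members differ (the site the caller failed to phase),
#'   \item its coding sequence has a premature stop codon (scanned through
#'     the frameshifted frame).
#' }
#'
#' @param solitary aligned sequence of the single-allele replicate
#' @param pair character vector of the two aligned sequences of the
#'   two-allele replicate
#' @param model \code{gene_model} of the locus
#' @return list: \code{spurious} (logical), \code{evidence} (named logical
#'   vector with the three criteria), \code{deletion_columns},
#'   \code{distinguishing_deletion_columns}
#' @export
spurious_deletion_check <- function(solitary, pair, model) {
  stopifnot(length(pair) == 2L)
  L <- model_length(model)
  if (nchar(solitary) != L || any(nchar(pair) != L))
    stop("sequences must share the locus alignment (", L, " columns)")
  cs <- strsplit(solitary, "")[[1]]
  c1 <- strsplit(pair[1], "")[[1]]
  c2 <- strsplit(pair[2], "")[[1]]
  seg <- model$segments
  in_exon <- logical(L)
  for (i in which(seg$kind == "exon")) in_exon[seg$start[i]:seg$end[i]] <- TRUE
  del <- cs == "-" & c1 != "-" & c2 != "-"
  del_exon <- which(del & in_exon)
  dist_del <- del_exon[c1[del_exon] != c2[del_exon]]
  cds <- extract_cds(solitary, model)
  evidence <- c(exon_deletion = length(del_exon) > 0L,
                deletion_at_distinguishing_site = length(dist_del) > 0L,
                premature_stop = !is.na(cds$premature_stop_at))
  list(spurious = all(evidence), evidence = evidence,
       deletion_columns = del_exon,
       distinguishing_deletion_columns = dist_del)
}

#' Reconcile two replicate call sets
#'
#' Identical allele-sequence sets are concordant. If one replicate calls
#' two alleles and the other a single different allele, the solitary
#' allele is tested for the spurious-deletion signature
#' (\code{\link{spurious_deletion_check}}); if all three criteria fire,
#' the two-allele call is kept and the pair is marked
#' \code{resolved_spurious_deletion}. Any other disagreement is
#' \code{discordant_unresolved} with both call sets preserved -- data are
#' never auto-dropped. Read support, when available, is annotated as soft
#' evidence only.
#'
#' @param r1,r2 \code{replicate_call_set}s for the same individual and
#'   locus
#' @param model \code{gene_model} of the locus
#' @return list of class \code{consensus_call}: \code{individual},
#'   \code{locus}, \code{alleles} (final call), \code{status},
#'   \code{evidence}, \code{replicates} (both input sets)
#' @export
reconcile <- function(r1, r2, model) {
  stopifnot(inherits(r1, "replicate_call_set"),
            inherits(r2, "replicate_call_set"))
  if (r1$individual != r2$individual || r1$locus != r2$locus)
    stop(sprintf("replicates disagree on identity: %s/%s vs %s/%s",
                 r1$individual, r1$locus, r2$individual, r2$locus))
  set1 <- sort(unique(unname(r1$alleles)))
  set2 <- sort(unique(unname(r2$alleles)))
  out <- function(alleles, status, evidence = NULL)
    structure(list(individual = r1$individual, locus = r1$locus,
                   alleles = alleles, status = status, evidence = evidence,
                   replicates = list(r1, r2)),
              class = "consensus_call")
  if (identical(set1, set2))
    return(out(r1$alleles, "concordant"))
  if (length(set1) + length(set2) == 3L) {
    solitary_set <- if (length(set1) == 1L) r1 else r2
    pair_set <- if (length(set1) == 1L) r2 else r1
    chk <- spurious_deletion_check(unname(solitary_set$alleles)[1],
                                   unique(unname(pair_set$alleles)), model)
    if (!is.null(solitary_set$read_support) && !is.null(pair_set$read_support))
      chk$evidence <- c(chk$evidence,
                        lower_read_support = max(solitary_set$read_support) <
                          min(pair_set$read_support))
    if (chk$spurious)
      return(out(pair_set$alleles, "resolved_spurious_deletion", chk))
    return(out(NULL, "discordant_unresolved", chk))
  }
  out(NULL, "discordant_unresolved")
}

#' @export
print.consensus_call <- function(x, ...) {
  cat(sprintf("consensus %s @ %s: %s (%d allele(s) kept)\n",
              x$individual, x$locus, x$status, length(x$alleles)))
  invisible(x)
}

#' QC report over a set of replicate call pairs
#'
#' Applies \code{\link{reconcile}} to every individual's replicate pair
#' at a locus and tabulates the outcome.
#'
#' @param replicate_calls list of per-individual lists with elements
#'   \code{r1} and \code{r2} (as produced by
#'   \code{\link{inject_artifacts}})
#' @param model \code{gene_model} of the locus
#' @return data.frame: individual, locus, status, n_alleles, evidence
#'   summary columns
#' @export
qc_scan <- function(replicate_calls, model) {
  rows <- lapply(replicate_calls, function(pair) {
    cc <- reconcile(pair$r1, pair$r2, model)
    ev <- cc$evidence$evidence
    data.frame(individual = cc$individual, locus = cc$locus,
               status = cc$status, n_alleles = length(cc$alleles),
               exon_deletion = if (is.null(ev)) NA else ev[["exon_deletion"]],
               at_distinguishing_site = if (is.null(ev)) NA
                 else ev[["deletion_at_distinguishing_site"]],
               premature_stop = if (is.null(ev)) NA else ev[["premature_stop"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
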