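#' Exon/intron gene models on a per-locus alignment
#'
#' An MHC class I gene model is an ordered series of exon and intron
#' segments (E1, I1, E2, ..., terminating in an exon) whose lengths are
#' given on the coordinate system of the per-locus multiple alignment:
#' alignment gap columns count towards segment length, so the same model
#' partitions every aligned allele of the locus.
#'
#' @param segments data.frame with columns \code{label} (e.g. "E1", "I1"),
#'   \code{kind} ("exon" or "intron") and \code{length} (positive integer,
#'   alignment columns).
#' @param locus locus identifier, e.g. "Patr-B".
#' @return An object of class \code{gene_model}: the validated segment table
#'   plus 1-based closed \code{start}/\code{end} alignment coordinates per
#'   segment.
#' @examples
#' m <- gene_model(data.frame(label = c("E1", "I1", "E2"),
#'                            kind = c("exon", "intron", "exon"),
#'                            length = c(4L, 3L, 3L)), locus = "toy")
#' region_slices(m)
#' @export
gene_model <- function(segments, locus = "locus") {
  stopifnot(is.data.frame(segments))
  need <- c("label", "kind", "length")
  if (!all(need %in% names(segments)))
    stop("gene model table needs columns: ", paste(need, collapse = ", "))
  if (nrow(segments) == 0L) stop("gene model has no segments")
  seg <- data.frame(label = as.character(segments$label),
                    kind = tolower(as.character(segments$kind)),
                    length = segments$length,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(seg))) {
    if (!seg$kind[i] %in% c("exon", "intron"))
      stop(sprintf("segment %d (%s): kind must be exon or intron, got '%s'",
                   i, seg$label[i], seg$kind[i]))
    if (is.na(seg$length[i]) || seg$length[i] < 1 ||
        seg$length[i] != as.integer(seg$length[i]))
      stop(sprintf("segment %d (%s): length must be a positive integer, got %s",
                   i, seg$label[i], seg$length[i]))
  }
  seg$length <- as.integer(seg$length)
  # strict alternation, exon first and last
  expect <- rep(c("exon", "intron"), length.out = nrow(seg))
  bad <- which(seg$kind != expect)
  if (length(bad))
    stop(sprintf("segments must alternate exon/intron starting with an exon; segment %d (%s) is %s",
                 bad[1], seg$label[bad[1]], seg$kind[bad[1]]))
  if (seg$kind[nrow(seg)] != "exon")
    stop("gene model must end with an exon")
  if (anyDuplicated(seg$label))
    stop("duplicate segment label: ",
         seg$label[duplicated(seg$label)][1])
  # labels sequential within kind: E1..En, I1..I(n-1)
  exp_lab <- ifelse(seg$kind == "exon",
                    paste0("E", cumsum(seg$kind == "exon")),
                    paste0("I", cumsum(seg$kind == "intron")))
  if (!all(seg$label == exp_lab))
    stop("segment labels must be sequential (",
         paste(exp_lab, collapse = ", "), "); got ",
         paste(seg$label, collapse = ", "))
  seg$end <- cumsum(seg$length)
  seg$start <- seg$end - seg$length + 1L
  structure(list(locus = locus, segments = seg),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %d exons, %d introns, %d alignment columns\n",
              x$locus, sum(x$segments$kind == "exon"),
              sum(x$segments$kind == "intron"), model_length(x)))
  print(x$segments[, c("label", "kind", "length", "start", "end")],
        row.names = FALSE)
  invisible(x)
}

#' Total alignment length covered by a gene model
#' @param model a \code{gene_model}
#' @export
model_length <- function(model) sum(model$segments$length)

#' Region slice table of a gene model
#'
#' @param model a \code{gene_model}
#' @return data.frame with \code{label}, \code{kind}, \code{start},
#'   \code{end} (1-based closed alignment columns). Slices tile the
#'   alignment without gaps or overlap.
#' @export
region_slices <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  model$segments[, c("label", "kind", "start", "end")]
}

#' Read a gene model from a TSV file
#'
#' Expected columns: \code{label}, \code{kind}, \code{length}. The locus
#' name is taken from a leading \code{# locus: <name>} comment if present,
#' otherwise from the file name.
#'
#' @param path path to the TSV file
#' @return a \code{gene_model}
#' @export
read_gene_model <- function(path) {
  first <- readLines(path, n = 1L)
  locus <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("^#\\s*locus:", first))
    locus <- trimws(sub("^#\\s*locus:", "", first))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  gene_model(tab, locus = locus)
}

#' Partition an aligned sequence into gene-model regions
#'
#' @param aligned_seq a single gapped DNA string whose length equals the
#'   model's total alignment length
#' @param model a \code{gene_model}
#' @return named character vector of subsequences, one per segment in model
#'   order; their concatenation reproduces \code{aligned_seq} exactly.
#' @export
partition_alignment <- function(aligned_seq, model) {
  stopifnot(inherits(model, "gene_model"), is.character(aligned_seq),
            length(aligned_seq) == 1L)
  L <- model_length(model)
  if (nchar(aligned_seq) != L)
    stop(sprintf("aligned sequence has %d columns but model '%s' spans %d",
                 nchar(aligned_seq), model$locus, L))
  seg <- model$segments
  out <- substring(aligned_seq, seg$start, seg$end)
  names(out) <- seg$label
  out
}

#' Extract the coding sequence (concatenated exons) of an aligned allele
#'
#' Exon slices are concatenated in model order and alignment gap characters
#' are removed. The result records whether the reading frame is intact
#' (length a multiple of 3) and the position of any premature stop codon.
#' Premature stops are scanned codon-by-codon even for frameshifted
#' sequences, since a frameshifting deletion typically brings a stop into
#' frame downstream.
#'
#' @param aligned_seq gapped DNA string of model length
#' @param model a \code{gene_model}
#' @param gap gap character, default \code{"-"}
#' @return list of class \code{coding_sequence} with elements
#'   \code{nucleotides}, \code{frame_ok}, \code{premature_stop_at}
#'   (1-based codon index, or NA), \code{n_codons}.
#' @export
extract_cds <- function(aligned_seq, model, gap = "-") {
  parts <- partition_alignment(aligned_seq, model)
  exon <- model$segments$kind == "exon"
  cds <- paste(parts[exon], collapse = "")
  cds <- gsub(gap, "", cds, fixed = TRUE)
  as_coding_sequence(cds)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# cache the standard genetic code so hot loops avoid repeated namespace
# lookups into Biostrings
.codon_cache <- new.env(parent = emptyenv())
codon_table <- function() {
  if (is.null(.codon_cache$code))
    .codon_cache$code <- Biostrings::GENETIC_CODE
  .codon_cache$code
}

#' Build a coding_sequence record from a bare (ungapped) CDS string
#' @param cds ungapped DNA string
#' @return a \code{coding_sequence}
#' @export
as_coding_sequence <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  n_codons <- n %/% 3L
  frame_ok <- n > 0L && n %% 3L == 0L
  premature <- NA_integer_
  if (n_codons >= 1L) {
    codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    is_stop <- codons %in% STOP_CODONS
    # a stop is premature unless it is the final codon of an in-frame CDS
    hit <- which(is_stop)
    if (length(hit)) {
      first <- hit[1]
      if (!(frame_ok && first == n_codons)) premature <- first
    }
  }
  structure(list(nucleotides = cds, frame_ok = frame_ok,
                 premature_stop_at = premature, n_codons = n_codons),
            class = "coding_sequence")
}

#' Translate a coding sequence
#'
#' Standard genetic code; codons containing IUPAC ambiguity codes or gaps
#' translate to "X" and never count as stops. Translation stops at
#' (and excludes) the first stop codon. A sequence is functional iff its
#' frame is intact and no premature stop occurs.
#'
#' @param cds a \code{coding_sequence} (see \code{\link{extract_cds}}) or a
#'   bare DNA string
#' @return list with \code{protein}, \code{functional} (logical) and
#'   \code{reason} (NA, "frameshift" or "premature_stop")
#' @export
translate_cds <- function(cds) {
  if (is.character(cds)) cds <- as_coding_sequence(cds)
  stopifnot(inherits(cds, "coding_sequence"))
  code <- codon_table()
  n_codons <- cds$n_codons
  protein <- ""
  if (n_codons >= 1L) {
    s <- cds$nucleotides
    codons <- substring(s, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"            # ambiguity/gap-containing codons
    stop_at <- which(codons %in% STOP_CODONS)
    keep <- if (length(stop_at)) seq_len(stop_at[1] - 1L) else seq_len(n_codons)
    protein <- paste(aa[keep], collapse = "")
  }
  reason <- NA_character_
  if (!cds$frame_ok) reason <- "frameshift"
  else if (!is.na(cds$premature_stop_at)) reason <- "premature_stop"
  list(protein = protein, functional = is.na(reason), reason = reason)
}

#' Is an aligned allele functional under a gene model?
#'
#' Convenience wrapper: extracts the CDS and reports whether it is in frame
#' with no premature stop codon.
#' @inheritParams extract_cds
#' @export
is_functional_allele <- function(aligned_seq, model, gap = "-") {
  cds <- extract_cds(aligned_seq, model, gap = gap)
  cds$frame_ok && is.na(cds$premature_stop_at)
}
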