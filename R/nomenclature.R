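#' MHC allele nomenclature
#'
#' Allele names follow the colon-delimited convention
#' \code{<locus>*<group>[:<protein>[:<synonymous>[:<noncoding>]]]}, e.g.
#' \code{Patr-A*15:01:01:01}. The four fields encode, in order, the allele
#' group, the protein (allotype), synonymous coding changes, and
#' intron/UTR changes; truncating the name therefore collapses alleles to
#' coarser equivalence classes:
#' \describe{
#'   \item{full}{all 4 fields -- distinct full-length sequences}
#'   \item{coding}{3 fields -- distinct coding region sequences}
#'   \item{protein}{2 fields -- distinct allotypes}
#'   \item{group}{1 field -- allele group}
#' }
#' Field comparison is on the zero-padded strings as written; locus
#' prefixes (Patr-/Papa-) are significant, so names never match across
#' species.
#'
#' @param s allele name string, e.g. "Patr-A*15:01:01:01"
#' @return \code{parse_allele_name}: a list of class \code{allele_name}
#'   with \code{locus} and \code{fields} (character vector, 1-4 elements).
#' @examples
#' a <- parse_allele_name("Patr-A*15:01:01:01")
#' format_allele_name(collapse_name(a, "protein"))
#' @export
parse_allele_name <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  star <- regexpr("*", s, fixed = TRUE)
  if (star < 0)
    stop(sprintf("malformed allele name '%s': no '*' separator", s))
  locus <- substr(s, 1L, star - 1L)
  rest <- substr(s, star + 1L, nchar(s))
  if (!grepl("^[A-Za-z][A-Za-z0-9.]*(-[A-Za-z0-9]+)?$", locus))
    stop(sprintf("malformed allele name '%s': bad locus before position %d",
                 s, star))
  if (!grepl("^[0-9]+(:[0-9]+){0,3}$", rest))
    stop(sprintf("malformed allele name '%s': bad field string after position %d",
                 s, star))
  structure(list(locus = locus,
                 fields = strsplit(rest, ":", fixed = TRUE)[[1]]),
            class = "allele_name")
}

#' @rdname parse_allele_name
#' @param a an \code{allele_name}
#' @export
format_allele_name <- function(a) {
  stopifnot(inherits(a, "allele_name"))
  paste0(a$locus, "*", paste(a$fields, collapse = ":"))
}

#' @export
print.allele_name <- function(x, ...) {
  cat(format_allele_name(x), "\n")
  invisible(x)
}

COLLAPSE_LEVELS <- c(group = 1L, protein = 2L, coding = 3L, full = 4L)

#' Collapse an allele name to a resolution level
#'
#' Truncates the name to the level's field count (a no-op if the name
#' already has fewer fields). Collapsing is idempotent and monotone:
#' partitions refine from group to full.
#'
#' @param a an \code{allele_name}, or a character vector of allele name
#'   strings (then a character vector is returned)
#' @param level one of "full", "coding", "protein", "group"
#' @export
collapse_name <- function(a, level = c("full", "coding", "protein", "group")) {
  level <- match.arg(level)
  k <- COLLAPSE_LEVELS[[level]]
  if (is.character(a)) {
    return(vapply(a, function(s) {
      p <- parse_allele_name(s)
      p$fields <- p$fields[seq_len(min(k, length(p$fields)))]
      format_allele_name(p)
    }, character(1), USE.NAMES = FALSE))
  }
  stopifnot(inherits(a, "allele_name"))
  a$fields <- a$fields[seq_len(min(k, length(a$fields)))]
  a
}

#' Flag allele names as known or novel against a reference catalogue
#'
#' A query is novel at a level iff its collapsed name matches no collapsed
#' reference name (case-insensitive locus). This is name-based novelty
#' against a user-supplied catalogue, not a sequence search.
#'
#' @param query character vector of allele names
#' @param reference character vector of known allele names (may be empty)
#' @param level collapse level at which to compare
#' @return character vector, "known" or "novel", one per query
#' @export
classify_novelty <- function(query, reference,
                             level = c("full", "coding", "protein", "group")) {
  level <- match.arg(level)
  canon <- function(x) {
    x <- collapse_name(x, level)
    # case-insensitive locus comparison
    vapply(x, function(s) {
      p <- parse_allele_name(s)
      paste0(tolower(p$locus), "*", paste(p$fields, collapse = ":"))
    }, character(1), USE.NAMES = FALSE)
  }
  ref <- if (length(reference)) canon(reference) else character(0)
  ifelse(canon(query) %in% ref, "known", "novel")
}

ABSENT_MARKERS <- c("–", "-", "—")

is_a_like_locus <- function(locus) grepl("(AL|A-like)$", locus, ignore.case = TRUE)

#' Read a diploid genotype table
#'
#' Expected TSV columns: \code{individual}, \code{taxon}, \code{locus},
#' \code{allele1}, \code{allele2}. A row carries one or two allele names;
#' a single name is by default treated as a homozygous call (the allele
#' counted twice in diversity computations). The absent marker
#' (en-dash or "-") in \code{allele1} is only legal at an A-like locus and
#' records confirmed absence of that locus; individuals with no row at a
#' locus are "untested" there.
#'
#' @param path TSV file path
#' @return data.frame of class \code{genotype_table} with columns
#'   \code{individual}, \code{taxon}, \code{locus}, \code{allele1},
#'   \code{allele2} (NA if single call), \code{absent} (logical).
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), fileEncoding = "UTF-8")
  need <- c("individual", "taxon", "locus", "allele1", "allele2")
  if (nrow(tab) == 0L) {
    warning("empty genotype table: ", path)
    tab <- data.frame(individual = character(0), taxon = character(0),
                      locus = character(0), allele1 = character(0),
                      allele2 = character(0), stringsAsFactors = FALSE)
  }
  if (!all(need %in% names(tab)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  genotype_table(tab[, need])
}

#' Construct / validate a genotype table from a data.frame
#' @param tab data.frame with columns individual, taxon, locus, allele1,
#'   allele2
#' @return validated \code{genotype_table}
#' @export
genotype_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (is.null(tab$allele2)) tab$allele2 <- NA_character_
  tab$absent <- !is.na(tab$allele1) & tab$allele1 %in% ABSENT_MARKERS
  errs <- character(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$absent[i]) {
      if (!is_a_like_locus(tab$locus[i]))
        errs <- c(errs, sprintf(
          "row %d (%s, %s): absent marker only allowed at an A-like locus",
          i, tab$individual[i], tab$locus[i]))
      if (!is.na(tab$allele2[i]))
        errs <- c(errs, sprintf(
          "row %d (%s): absent marker with a second allele", i,
          tab$individual[i]))
      next
    }
    for (al in c(tab$allele1[i], tab$allele2[i])) {
      if (is.na(al)) next
      ok <- tryCatch({parse_allele_name(al); TRUE},
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok))
        errs <- c(errs, sprintf("row %d (%s, %s): %s", i, tab$individual[i],
                                tab$locus[i], ok))
    }
    if (is.na(tab$allele1[i]) && !is.na(tab$allele2[i]))
      errs <- c(errs, sprintf("row %d (%s): allele2 without allele1", i,
                              tab$individual[i]))
  }
  dup <- duplicated(tab[, c("individual", "locus")])
  if (any(dup))
    errs <- c(errs, sprintf("duplicate individual x locus row: %s x %s",
                            tab$individual[dup][1], tab$locus[dup][1]))
  if (length(errs))
    stop("invalid genotype table:\n  ", paste(errs, collapse = "\n  "))
  tab$absent[is.na(tab$allele1)] <- FALSE
  class(tab) <- c("genotype_table", "data.frame")
  tab
}

#' Write a genotype table as TSV
#' @param gt a \code{genotype_table}
#' @param path output path
#' @export
write_genotype_table <- function(gt, path) {
  out <- as.data.frame(gt)[, c("individual", "taxon", "locus",
                               "allele1", "allele2")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Expand genotype rows into one call per chromosome
#'
#' Each present row yields two calls: the two alleles of a heterozygote, or
#' the single allele duplicated for a homozygous(-candidate) row (set
#' \code{homozygous_single = FALSE} to keep single calls as one allele,
#' treating them as possible dropout instead).
#'
#' @param gt a \code{genotype_table}
#' @param homozygous_single duplicate single calls? default TRUE
#' @return data.frame with columns individual, taxon, locus, allele
#' @export
genotype_calls <- function(gt, homozygous_single = TRUE) {
  gt <- gt[!gt$absent & !is.na(gt$allele1), , drop = FALSE]
  a2 <- ifelse(is.na(gt$allele2),
               if (homozygous_single) gt$allele1 else NA_character_,
               gt$allele2)
  long <- rbind(
    data.frame(individual = gt$individual, taxon = gt$taxon,
               locus = gt$locus, allele = gt$allele1,
               stringsAsFactors = FALSE),
    data.frame(individual = gt$individual, taxon = gt$taxon,
               locus = gt$locus, allele = a2, stringsAsFactors = FALSE))
  long <- long[!is.na(long$allele), , drop = FALSE]
  long[order(match(long$individual, gt$individual)), , drop = FALSE]
}
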