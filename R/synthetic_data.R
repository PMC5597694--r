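#' Synthetic MHC allele pools and diploid genotypes
#'
#' The generator produces, per locus, a pool of K distinct gap-free
#' aligned alleles derived from one ancestral sequence by region-specific
#' substitution (expected substitutions per site set per exon/intron, so
#' diversity can be concentrated in the peptide-binding exons), allele
#' frequencies from a symmetric Dirichlet, diploid genotypes for any
#' number of taxa with a controllable diversity ratio, and optional
#' replicate-call artifacts (spurious frameshifting 1-bp deletion
#' alleles). Pools contain no indels, so the alignment is trivial and the
#' diversity statistics are exercised free of alignment ambiguity.
#'
#' @name synthetic_data
NULL

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# random ancestral aligned sequence with a functional CDS:
# non-stop codons threaded through the exons (terminal stop last),
# random bases in the introns
make_ancestral <- function(model, seed = NULL) {
  with_seed(seed, {
    seg <- model$segments
    exon_total <- sum(seg$length[seg$kind == "exon"])
    if (exon_total %% 3L != 0L)
      stop("model exon lengths must sum to a multiple of 3 for simulation")
    n_cod <- exon_total %/% 3L
    cds <- c(sample(NON_STOP_CODONS, n_cod - 1L, replace = TRUE), "TGA")
    cds_chars <- strsplit(paste(cds, collapse = ""), "")[[1]]
    out <- character(model_length(model))
    pos <- 1L
    for (i in seq_len(nrow(seg))) {
      idx <- seg$start[i]:seg$end[i]
      if (seg$kind[i] == "exon") {
        out[idx] <- cds_chars[pos:(pos + seg$length[i] - 1L)]
        pos <- pos + seg$length[i]
      } else {
        out[idx] <- sample(c("A", "C", "G", "T"), seg$length[i], replace = TRUE)
      }
    }
    paste(out, collapse = "")
  })
}

#' Region-specific mutation-density presets
#'
#' Expected substitutions per site (relative to the ancestral sequence)
#' per gene-model segment. The "AB" profile concentrates diversity in
#' exons 2 and 3 (the peptide-binding domains of class I A/B genes), the
#' "C" profile in exon 5, "uniform" applies the base rate everywhere.
#'
#' @param model a \code{gene_model}
#' @param profile "AB", "C" or "uniform"
#' @param base background rate per site (default 0.005)
#' @param hot hotspot rate per site (default 0.04)
#' @return named numeric vector over segment labels
#' @export
default_region_rates <- function(model, profile = c("AB", "C", "uniform"),
                                 base = 0.005, hot = 0.04) {
  profile <- match.arg(profile)
  lab <- model$segments$label
  rates <- stats::setNames(rep(base, length(lab)), lab)
  hotspots <- switch(profile, AB = c("E2", "E3"), C = "E5", uniform = character(0))
  rates[intersect(hotspots, lab)] <- hot
  rates
}

#' Generate a pool of distinct functional alleles for one locus
#'
#' Each allele is the ancestral sequence with Poisson(rate x length)
#' substitutions per segment; alleles whose CDS is non-functional or that
#' duplicate an earlier allele are re-drawn, so the pool is guaranteed
#' distinct with all CDSs functional. Allele names are assigned in
#' nomenclature-valid 4-field format, with fields reflecting the protein /
#' coding / full-length equivalence classes actually realised in the pool.
#'
#' @param model a \code{gene_model}
#' @param K number of alleles (>= 1)
#' @param region_rates named per-segment rates (see
#'   \code{\link{default_region_rates}}) or a single number
#' @param seed RNG seed
#' @param locus locus name used as the allele-name prefix (default:
#'   \code{model$locus})
#' @param ancestral optional ancestral sequence to share between pools
#'   (e.g. two taxa at one locus); default: drawn from the seed
#' @param diversity_scale multiplier on all rates (default 1)
#' @param max_tries re-draw attempts per allele before giving up
#' @return object of class \code{allele_pool}: \code{sequences} (named),
#'   \code{ancestral}, \code{model}, \code{locus}, \code{rates}
#' @export
generate_pool <- function(model, K, region_rates, seed = NULL,
                          locus = model$locus, ancestral = NULL,
                          diversity_scale = 1, max_tries = 500L) {
  stopifnot(K >= 1, diversity_scale > 0)
  seg <- model$segments
  if (length(region_rates) == 1L && is.null(names(region_rates)))
    region_rates <- stats::setNames(rep(region_rates, nrow(seg)), seg$label)
  if (!all(seg$label %in% names(region_rates)))
    stop("region_rates must cover every segment label")
  rates <- region_rates[seg$label] * diversity_scale
  if (any(rates < 0)) stop("rates must be >= 0")
  if (is.null(ancestral)) ancestral <- make_ancestral(model, seed = seed)
  anc_chars <- strsplit(ancestral, "")[[1]]
  bases <- c("A", "C", "G", "T")
  with_seed(if (is.null(seed)) NULL else derive_seed(seed, "pool"), {
    seqs <- character(K)
    for (k in seq_len(K)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        chars <- anc_chars
        for (i in seq_len(nrow(seg))) {
          nm <- stats::rpois(1L, rates[i] * seg$length[i])
          if (nm == 0L) next
          nm <- min(nm, seg$length[i])
          cols <- seg$start[i] + sample.int(seg$length[i], nm) - 1L
          for (col in cols)
            chars[col] <- sample(setdiff(bases, chars[col]), 1L)
        }
        s <- paste(chars, collapse = "")
        if (k == 1L && K == 1L && all(rates == 0)) { seqs[k] <- s; ok <- TRUE; break }
        if (s %in% seqs[seq_len(k - 1L)]) next
        if (!is_functional_allele(s, model)) next
        seqs[k] <- s; ok <- TRUE; break
      }
      if (!ok)
        stop(sprintf(
          "could not draw %d distinct functional alleles (stuck at %d); increase region_rates",
          K, k - 1L))
    }
    names(seqs) <- name_pool_alleles(seqs, model, locus)
    structure(list(sequences = seqs, ancestral = ancestral, model = model,
                   locus = locus, rates = rates),
              class = "allele_pool")
  })
}

# 4-field names whose truncations mirror the protein/coding/full classes
name_pool_alleles <- function(seqs, model, locus) {
  cds <- vapply(seqs, function(s) extract_cds(s, model)$nucleotides, character(1))
  prot <- vapply(cds, function(c) translate_cds(c)$protein, character(1))
  g <- match(prot, unique(prot))                       # protein class
  syn <- integer(length(seqs)); full <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    same_prot <- which(g == g[i])
    cds_classes <- unique(cds[same_prot])
    syn[i] <- match(cds[i], cds_classes)
    same_cds <- same_prot[cds[same_prot] == cds[i]]
    full[i] <- match(i, same_cds)
  }
  sprintf("%s*%02d:01:%02d:%02d", locus, g, syn, full)
}

# restrict aligned sequences to a region selection (model order)
cut_regions <- function(seqs, model, regions = NULL) {
  seg <- model$segments
  if (is.null(regions)) regions <- seg$label[seg$kind == "exon"]
  if (identical(regions, "all")) regions <- seg$label
  keep <- seg[seg$label %in% regions, , drop = FALSE]
  vapply(seqs, function(s)
    paste(substring(s, keep$start, keep$end), collapse = ""), character(1))
}

#' Expected sample nucleotide diversity of a pool under given frequencies
#'
#' For 2n sequences drawn i.i.d. with frequencies f over the pool, the
#' expectation of the sample pi equals the quadratic form
#' sum_kl f_k f_l pi_kl over the pool's pairwise per-site differences
#' (diagonal zero), restricted to the chosen regions. This closed form
#' scores parameter recovery of the diversity estimator.
#'
#' @param pool an \code{allele_pool}
#' @param freqs allele frequencies over the pool (sum to 1)
#' @param regions region selection as in \code{\link{build_matrix}}
#'   (default: all exons)
#' @return expected pi (scalar)
#' @export
expected_pi <- function(pool, freqs, regions = NULL) {
  stopifnot(inherits(pool, "allele_pool"),
            length(freqs) == length(pool$sequences),
            abs(sum(freqs) - 1) < 1e-8)
  cut <- cut_regions(pool$sequences, pool$model, regions)
  P <- pairwise_pi(unname(cut))$P
  drop(t(freqs) %*% P %*% freqs)
}

rdirichlet1 <- function(K, conc) {
  g <- stats::rgamma(K, shape = conc, rate = 1)
  if (all(g == 0)) g <- rep(1, K)
  g / sum(g)
}

#' Sample diploid genotypes from an allele pool
#'
#' Each of n individuals draws two alleles independently from the pool
#' frequencies; homozygotes arise naturally and are written as
#' single-call rows, matching the published-table convention.
#'
#' @param pool an \code{allele_pool}
#' @param n number of individuals
#' @param taxon taxon label for the rows
#' @param freqs allele frequencies (default: symmetric Dirichlet draw)
#' @param freq_concentration Dirichlet concentration if freqs is NULL
#' @param seed RNG seed
#' @param prefix individual-id prefix (default: taxon)
#' @return list: \code{genotypes} (a \code{genotype_table}), \code{freqs}
#' @export
sample_genotypes <- function(pool, n, taxon, freqs = NULL,
                             freq_concentration = 1, seed = NULL,
                             prefix = taxon) {
  K <- length(pool$sequences)
  with_seed(seed, {
    if (is.null(freqs)) freqs <- rdirichlet1(K, freq_concentration)
    stopifnot(length(freqs) == K, abs(sum(freqs) - 1) < 1e-8)
    a1 <- sample.int(K, n, replace = TRUE, prob = freqs)
    a2 <- sample.int(K, n, replace = TRUE, prob = freqs)
    nm <- names(pool$sequences)
    tab <- data.frame(
      individual = sprintf("%s_%02d", prefix, seq_len(n)),
      taxon = taxon, locus = pool$locus,
      allele1 = nm[a1],
      allele2 = ifelse(a1 == a2, NA_character_, nm[a2]),
      stringsAsFactors = FALSE)
    list(genotypes = genotype_table(tab), freqs = freqs)
  })
}

#' Simulation configuration
#'
#' @param models named list of \code{gene_model}s (base loci)
#' @param taxa data.frame with columns \code{label}, \code{prefix} (allele
#'   name prefix), \code{n} (individuals), \code{diversity_scale}
#'   (multiplier on all region rates), and optionally
#'   \code{freq_concentration}
#' @param K alleles per locus per taxon pool
#' @param rate_profiles named character vector: region-rate profile per
#'   base locus ("AB", "C" or "uniform"), see
#'   \code{\link{default_region_rates}}
#' @param base_rate,hot_rate background and hotspot substitution densities
#' @param freq_concentration default Dirichlet concentration
#' @param artifact_rate probability a heterozygous call yields a spurious
#'   deletion replicate artifact
#' @param seed base seed; every stage derives its own stream from it
#' @return list of class \code{simulation_config}
#' @export
simulation_config <- function(models, taxa, K = 12L,
                              rate_profiles = NULL,
                              base_rate = 0.005, hot_rate = 0.04,
                              freq_concentration = 1,
                              artifact_rate = 0, seed = 1L) {
  stopifnot(is.list(models), !is.null(names(models)),
            is.data.frame(taxa),
            all(c("label", "prefix", "n", "diversity_scale") %in% names(taxa)),
            all(taxa$diversity_scale > 0), all(taxa$n >= 1), K >= 1,
            artifact_rate >= 0, artifact_rate <= 1)
  if (is.null(rate_profiles))
    rate_profiles <- stats::setNames(rep("uniform", length(models)), names(models))
  if (!"freq_concentration" %in% names(taxa))
    taxa$freq_concentration <- freq_concentration
  structure(list(models = models, taxa = taxa, K = as.integer(K),
                 rate_profiles = rate_profiles, base_rate = base_rate,
                 hot_rate = hot_rate, artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Packaged two-taxon scenario
#'
#' Two taxa of 20 diploid individuals (matching the study's per-taxon
#' sample size) at three class I loci: an A- and B-like locus with
#' diversity concentrated in exons 2/3 and a C-like locus with the
#' hotspot in exon 5. The second taxon's pool is generated at a reduced
#' diversity scale with a skewed (dominant-allele) frequency
#' distribution, emulating the reduced and more uneven bonobo diversity.
#'
#' @param seed base seed
#' @param n individuals per taxon
#' @param diversity_ratio rate multiplier of the low-diversity taxon
#'   relative to the high-diversity taxon (default 0.3)
#' @param artifact_rate replicate artifact probability (default 0)
#' @return a \code{simulation_config}
#' @export
two_taxon_scenario <- function(seed = 1L, n = 20L, diversity_ratio = 0.3,
                               artifact_rate = 0) {
  models <- list(A = pan_gene_model("A"), B = pan_gene_model("B"),
                 C = pan_gene_model("C"))
  taxa <- data.frame(
    label = c("taxonHi", "taxonLo"),
    prefix = c("SimHi", "SimLo"),
    n = n, diversity_scale = c(1, diversity_ratio),
    freq_concentration = c(1, 0.4),
    stringsAsFactors = FALSE)
  simulation_config(models, taxa, K = 12L,
                    rate_profiles = c(A = "AB", B = "AB", C = "C"),
                    artifact_rate = artifact_rate, seed = seed)
}

#' Simulate a complete dataset
#'
#' For every base locus one ancestral sequence is drawn and shared by all
#' taxa, so their pools live on a common alignment; each taxon then gets
#' its own pool (rates scaled by its \code{diversity_scale}), allele
#' frequencies and diploid genotypes. Locus names are taxon-prefixed
#' (e.g. "SimHi-B"), mirroring species-specific nomenclature prefixes.
#' With \code{artifact_rate > 0}, duplicate replicate call sets with
#' injected spurious-deletion artifacts are generated per locus.
#'
#' @param config a \code{simulation_config}
#' @return list of class \code{simulated_dataset}: \code{genotypes}
#'   (combined \code{genotype_table}), \code{sequences} (all aligned
#'   alleles, named), \code{models} (per prefixed locus name),
#'   \code{pools}, \code{truth} (per taxon x locus: freqs and expected
#'   all-exons pi), \code{replicates} (per locus, see
#'   \code{\link{inject_artifacts}}), \code{config}
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gt_rows <- list(); seqs <- character(0); models <- list(); pools <- list()
  truth <- list(); replicates <- list()
  for (lname in names(config$models)) {
    model <- config$models[[lname]]
    rates <- default_region_rates(model, config$rate_profiles[[lname]],
                                  base = config$base_rate,
                                  hot = config$hot_rate)
    anc <- make_ancestral(model, seed = derive_seed(config$seed,
                                                    paste0("anc/", lname)))
    for (t in seq_len(nrow(config$taxa))) {
      tx <- config$taxa[t, ]
      locus <- paste0(tx$prefix, "-", lname)
      pool <- generate_pool(model, config$K, rates,
                            seed = derive_seed(config$seed,
                                               paste0("pool/", locus)),
                            locus = locus, ancestral = anc,
                            diversity_scale = tx$diversity_scale)
      sg <- sample_genotypes(pool, tx$n, taxon = tx$label,
                             freq_concentration = tx$freq_concentration,
                             seed = derive_seed(config$seed,
                                                paste0("geno/", locus)),
                             prefix = tx$prefix)
      gt_rows[[locus]] <- as.data.frame(sg$genotypes)
      seqs <- c(seqs, pool$sequences)
      models[[locus]] <- model
      pools[[locus]] <- pool
      truth[[locus]] <- list(taxon = tx$label, base_locus = lname,
                             freqs = sg$freqs,
                             expected_pi_exons = expected_pi(pool, sg$freqs))
    }
  }
  gt <- genotype_table(do.call(rbind, c(gt_rows, list(make.row.names = FALSE))))
  ds <- structure(list(genotypes = gt, sequences = seqs, models = models,
                       pools = pools, truth = truth, replicates = NULL,
                       config = config),
                  class = "simulated_dataset")
  if (config$artifact_rate > 0) {
    ds$replicates <- lapply(names(models), function(locus)
      inject_artifacts(gt, seqs, models[[locus]], locus,
                       artifact_rate = config$artifact_rate,
                       seed = derive_seed(config$seed,
                                          paste0("artifact/", locus))))
    names(ds$replicates) <- names(models)
  }
  ds
}

#' Inject spurious-deletion replicate artifacts
#'
#' Builds duplicate replicate call sets for every individual at a locus
#' (both replicates carrying the true alleles) and, with the given
#' probability at heterozygous calls, replaces one replicate by a solitary
#' artifact allele: a copy of one true allele with a 1-bp deletion at an
#' exon column that distinguishes the two true alleles. The deletion
#' column (and donor allele) is chosen so the frameshifted CDS carries a
#' premature stop codon, which is the defining signature of the artifact;
#' heterozygous calls where no distinguishing exon column yields a stop
#' are skipped and logged in the truth record.
#'
#' @param gt a \code{genotype_table}
#' @param seqs named aligned allele sequences
#' @param model \code{gene_model} of the locus
#' @param locus locus name in \code{gt}
#' @param artifact_rate per-heterozygote artifact probability
#' @param seed RNG seed
#' @return list: \code{calls} (list of per-individual lists with
#'   \code{r1}, \code{r2} replicate call sets), \code{truth} (data.frame:
#'   individual, artifact, column)
#' @export
inject_artifacts <- function(gt, seqs, model, locus, artifact_rate,
                             seed = NULL) {
  sub <- gt[gt$locus == locus & !gt$absent & !is.na(gt$allele1), , drop = FALSE]
  with_seed(seed, {
    calls <- list(); truth <- list()
    for (i in seq_len(nrow(sub))) {
      ind <- sub$individual[i]
      al <- unique(stats::na.omit(c(sub$allele1[i], sub$allele2[i])))
      true_set <- stats::setNames(unname(seqs[al]), al)
      r1 <- replicate_call_set(ind, locus, 1L, true_set)
      r2 <- replicate_call_set(ind, locus, 2L, true_set)
      art_col <- NA_integer_; made <- FALSE
      hetero <- length(al) == 2L && true_set[1] != true_set[2]
      if (hetero && stats::runif(1) < artifact_rate) {
        sp <- make_spurious_deletion(true_set[[1]], true_set[[2]], model)
        if (!is.null(sp)) {
          solitary <- stats::setNames(sp$seq, paste0(ind, "_artifact"))
          corrupt <- sample(1:2, 1L)
          if (corrupt == 1L) r1 <- replicate_call_set(ind, locus, 1L, solitary)
          else r2 <- replicate_call_set(ind, locus, 2L, solitary)
          art_col <- sp$column; made <- TRUE
        } else {
          message("inject_artifacts: no stop-inducing deletion for ", ind,
                  "; left concordant")
        }
      }
      calls[[ind]] <- list(r1 = r1, r2 = r2)
      truth[[ind]] <- data.frame(individual = ind, artifact = made,
                                 column = art_col, stringsAsFactors = FALSE)
    }
    list(calls = calls, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

# chimera-of-two artifact: 1-bp deletion at a random distinguishing exon
# column such that the shifted frame hits a premature stop
make_spurious_deletion <- function(x, y, model) {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  seg <- model$segments
  in_exon <- logical(length(cx))
  for (i in which(seg$kind == "exon")) in_exon[seg$start[i]:seg$end[i]] <- TRUE
  cand <- which(in_exon & cx != cy & cx != "-" & cy != "-")
  if (!length(cand)) return(NULL)
  cand <- cand[sample.int(length(cand))]
  for (donor in list(cx, cy)) for (col in cand) {
    chars <- donor; chars[col] <- "-"
    s <- paste(chars, collapse = "")
    if (!is.na(extract_cds(s, model)$premature_stop_at))
      return(list(seq = s, column = col))
  }
  NULL
}
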