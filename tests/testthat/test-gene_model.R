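test_that("gene models validate structure and compute slices", {
  b <- pan_gene_model("B")
  expect_equal(sum(b$segments$kind == "exon"), 7)
  expect_equal(sum(b$segments$kind == "intron"), 6)
  expect_equal(b$segments$length[b$segments$label == "I3"], 574)
  expect_equal(b$segments$length[b$segments$label == "E7"], 44)

  a <- pan_gene_model("A")
  expect_equal(sum(a$segments$kind == "exon"), 8)
  expect_equal(sum(a$segments$kind == "intron"), 7)
  expect_equal(a$segments$length[a$segments$label == "I3"], 583)
  expect_equal(a$segments$length[a$segments$label == "E8"], 5)

  cm <- pan_gene_model("C")
  expect_equal(cm$segments$length[cm$segments$label == "I3"], 588)

  # slices tile the alignment: contiguous, widths match lengths
  sl <- region_slices(b)
  expect_equal(sl$start[1], 1)
  expect_equal(sl$end[nrow(sl)], model_length(b))
  expect_true(all(sl$start[-1] == sl$end[-nrow(sl)] + 1))
  expect_equal(sl$end - sl$start + 1, b$segments$length)

  # degenerate single-exon model
  m1 <- gene_model(data.frame(label = "E1", kind = "exon", length = 10))
  expect_equal(model_length(m1), 10)
})

test_that("invalid gene models are rejected with the offending row named", {
  expect_error(gene_model(data.frame(label = c("E1", "E2"),
                                     kind = c("exon", "exon"),
                                     length = c(5, 5))),
               "alternate")
  expect_error(gene_model(data.frame(label = c("E1", "I1"),
                                     kind = c("exon", "intron"),
                                     length = c(5, 5))),
               "end with an exon")
  expect_error(gene_model(data.frame(label = "E1", kind = "exon", length = 0)),
               "positive")
  expect_error(gene_model(data.frame(label = c("E1", "I1", "E1"),
                                     kind = c("exon", "intron", "exon"),
                                     length = c(3, 3, 3))),
               "duplicate|sequential")
})

test_that("partition splits by coordinates and round-trips", {
  m <- toy_model()
  p <- partition_alignment("ACGTACGTAC", m)
  expect_equal(unname(p), c("ACGT", "ACG", "TAC"))
  expect_equal(names(p), c("E1", "I1", "E2"))

  expect_error(partition_alignment("ACGT", m), "4 columns.*10|10")

  # round-trip property over random gapped sequences
  set.seed(11)
  for (i in 1:20) {
    s <- random_seqs(1, 10, gap_prob = 0.2)
    expect_identical(paste(partition_alignment(s, m), collapse = ""), s)
  }

  # width of a named slice follows the model
  cm <- pan_gene_model("C")
  s <- random_seqs(1, model_length(cm))
  expect_equal(nchar(partition_alignment(s, cm)[["I3"]]), 588)
})

test_that("CDS extraction strips gaps, detects frame and premature stops", {
  m <- frame_model()
  # canonical ORF: ATG AAA | intron | GCC TGA
  cds <- extract_cds(paste0("ATGAAA", "gtag", "GCCTGA"), m)
  expect_equal(cds$nucleotides, "ATGAAAGCCTGA")
  expect_true(cds$frame_ok)
  expect_true(is.na(cds$premature_stop_at))

  # premature stop at the second codon
  cds2 <- as_coding_sequence("ATGTAAAAATGA")
  expect_equal(cds2$premature_stop_at, 2L)

  # in-exon gap removal shortens the CDS by the gap count
  gapped <- paste0("ATG-AA", "GTAG", "GCCTGA")
  cds3 <- extract_cds(gapped, m)
  expect_equal(nchar(cds3$nucleotides), 11)
  expect_false(cds3$frame_ok)

  # frameshifting 1-bp deletion in a functional allele brings a stop
  # into frame downstream: ATG CTA AAC TGA loses column 4
  m2 <- gene_model(data.frame(label = "E1", kind = "exon", length = 12))
  expect_true(is.na(extract_cds("ATGCTAAACTGA", m2)$premature_stop_at))
  shifted <- extract_cds("ATG-TAAACTGA", m2)
  expect_false(shifted$frame_ok)
  expect_equal(shifted$premature_stop_at, 2L)
})

test_that("translation follows the standard code with ambiguity to X", {
  expect_equal(translate_cds("ATGGCCTGA")$protein, "MA")
  expect_true(translate_cds("ATGGCCTGA")$functional)

  early <- translate_cds(paste0("ATGTGA", strrep("AAA", 8)))
  expect_false(early$functional)
  expect_equal(early$reason, "premature_stop")

  fs <- translate_cds(as_coding_sequence("ATGGCCA"))
  expect_false(fs$functional)
  expect_equal(fs$reason, "frameshift")

  expect_equal(translate_cds("ATGNNNTGA")$protein, "MX")
  # ambiguity codes never count as stop: TRA could read TGA but stays X
  expect_equal(translate_cds("ATGTRATGA")$protein, "MX")
  expect_true(translate_cds("ATGTRATGA")$functional)
})

test_that("gene model TSV round-trips through read_gene_model", {
  m <- pan_gene_model("B")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# locus: B-copy",
               "label\tkind\tlength",
               sprintf("%s\t%s\t%d", m$segments$label, m$segments$kind,
                       m$segments$length)), tmp)
  m2 <- read_gene_model(tmp)
  expect_equal(m2$locus, "B-copy")
  expect_equal(m2$segments$length, m$segments$length)
})
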