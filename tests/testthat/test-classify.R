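# Junction, pair, frame, motif and isoform classifiers.

two_gene_ann <- function() {
  build_annotation(rbind(
    gene_features("GA", "chr1", "+", iv(c(101, 301), c(200, 400))),
    gene_features("GB", "chr1", "+", iv(c(1101, 1301), c(1200, 1400)))
  ))
}

test_that("classify_junction combines boundary roles into the four classes", {
  ann <- two_gene_ann()
  cl <- function(p5, p3) classify_junction(
    make_call("GA", "GB", "chr1", p5, "+", "chr1", p3, "+"), ann)
  expect_equal(cl(200, 1101), "EE")
  expect_equal(cl(200, 1150), "EM")
  expect_equal(cl(150, 1301), "ME")
  expect_equal(cl(150, 1350), "MM")
  ## outside-gene breakpoints collapse into MM (no fifth class)
  expect_equal(cl(250, 1101), "ME")
  expect_equal(cl(250, 1250), "MM")
  expect_error(classify_junction(
    make_call("GA", "NOPE", "chr1", 200, "+", "chr1", 1101, "+"), ann),
    "absent")
})

test_that("exhaustive junction-class grid matches the brute-force oracle", {
  strands <- c("+", "-")
  for (s5 in strands) for (s3 in strands) {
    ann <- build_annotation(rbind(
      gene_features("GA", "chr1", s5, iv(c(101, 301), c(200, 400))),
      gene_features("GB", "chr2", s3, iv(c(1101, 1301), c(1200, 1400)))
    ))
    exA <- list(ann$genes$GA$transcripts[[1]]$exons)
    exB <- list(ann$genes$GB$transcripts[[1]]$exons)
    code <- function(r) if (r == "exon_end") "E" else "M"
    for (p5 in seq(95, 405, by = 7)) for (p3 in seq(1095, 1405, by = 7)) {
      call <- make_call("GA", "GB", "chr1", p5, s5, "chr2", p3, s3)
      want <- paste0(code(oracle_boundary_role(exA, s5, p5, "donor")),
                     code(oracle_boundary_role(exB, s3, p3, "acceptor")))
      expect_identical(classify_junction(call, ann), want)
    }
  }
})

test_that("classify_pair applies chromosome, strand, order and gap rules", {
  ann <- build_annotation(rbind(
    gene_features("A", "chr1", "+", iv(c(1001, 2001), c(1500, 2500))),
    gene_features("B", "chr1", "+", iv(c(7501, 8001), c(7800, 8500))),
    gene_features("C", "chr7", "+", iv(c(501, 901), c(700, 1100))),
    gene_features("D", "chr1", "-", iv(c(20001, 21001), c(20500, 21500))),
    gene_features("E", "chr1", "+", iv(c(200001, 201001), c(200500, 201500)))
  ))
  pc <- function(g5, g3, ...) classify_pair(
    make_call(g5, g3, "chr1", 1100, "+", "chr1", 8100, "+"), ann, ...)
  expect_equal(pc("A", "C"), "inter_chromosomal")
  ## same chr, same strand, 5 kb gap, correct order
  expect_equal(pc("A", "B"), "read_through")
  expect_equal(pc("B", "A"), "intra_other")       # order violated
  expect_equal(pc("A", "D"), "intra_other")       # opposite strands
  expect_equal(pc("A", "E"), "intra_other")       # gap > 100 kb
  expect_equal(pc("A", "E", cfg = pair_class_config(readthrough_max_gap = 3e5)),
               "read_through")
  ## intervening same-strand gene check
  expect_equal(pc("A", "E", cfg = pair_class_config(
    readthrough_max_gap = 3e5,
    require_no_intervening_same_strand_gene = TRUE)), "intra_other")
})

test_that("read-through on the minus strand requires genomically reversed order", {
  ann <- build_annotation(rbind(
    gene_features("U", "chr1", "-", iv(c(9001, 9501), c(9300, 9800))),
    gene_features("V", "chr1", "-", iv(c(1001, 1501), c(1300, 1800)))
  ))
  ## U (downstream start genomically higher) is upstream in transcription
  expect_equal(classify_pair(
    make_call("U", "V", "chr1", 9001, "-", "chr1", 1800, "-"), ann),
    "read_through")
  expect_equal(classify_pair(
    make_call("V", "U", "chr1", 1001, "-", "chr1", 9800, "-"), ann),
    "intra_other")
})

test_that("predict_frame agrees with a codon-walk oracle on a fused toy CDS", {
  ## gene A: exon [1,120], CDS [1,60]; gene B: exon [1001,1120], CDS [1001,1060]
  ## fusing after A base 30 (phase of base 30 is (30-1)%%3 = 2, codon complete)
  ## to B base at CDS offset d keeps the walk iff d %% 3 == 0
  ann <- build_annotation(rbind(
    gene_features("A", "chr1", "+", iv(1, 120), cds = iv(1, 60)),
    gene_features("B", "chr2", "+", iv(1001, 1120), cds = iv(1001, 1060))
  ))
  genomeA <- rand_dna(120, seed = 5)
  genomeB <- rand_dna(1120, seed = 6)
  protein_of <- function(p5, p3) {
    fused <- paste0(substr(genomeA, 1, p5), substr(genomeB, p3, 1060))
    n_cod <- nchar(fused) %/% 3
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(fused, 1, 3 * n_cod)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  ## downstream-intact protein oracle: translation of B's own CDS from the
  ## next full codon must appear inside the fused protein when in frame
  b_prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(genomeB, 1004, 1060)), no.init.codon = TRUE))
  b_core <- substr(b_prot, 1, nchar(b_prot) - 1)   # drop last partial-risk aa
  for (d in 0:5) {
    call <- make_call("A", "B", "chr1", 30, "+", "chr2", 1001 + d, "+")
    got <- predict_frame(call, ann)
    want <- if (d %% 3 == 0) "in_frame" else "frame_shift"
    expect_identical(got, want)
    if (d == 3)
      expect_true(grepl(b_core, protein_of(30, 1001 + d), fixed = TRUE))
  }
  ## 5'UTR / noncoding side -> na
  expect_identical(predict_frame(
    make_call("A", "B", "chr1", 30, "+", "chr2", 1100, "+"), ann), "na")
  annnc <- build_annotation(rbind(
    gene_features("A", "chr1", "+", iv(1, 120), cds = iv(1, 60)),
    gene_features("B", "chr2", "+", iv(1001, 1120))
  ))
  expect_identical(predict_frame(
    make_call("A", "B", "chr1", 30, "+", "chr2", 1030, "+"), annnc), "na")
})

test_that("splice_motifs reads the canonical contexts on either strand", {
  ##            1234567890123
  chr <- paste0("CCCCAGGTCCCCC")   # AG ends at pos 6, GT at 7-8
  genome <- c(chrP = chr, chrM = revcomp(chr))
  call_p <- make_call("A", "B", "chrP", 6, "+", "chrP", 6, "+")
  m <- splice_motifs(call_p, genome)
  expect_true(m$donor_motif)
  ## acceptor wants AG then G: "AGG" ending at pos 7
  expect_true(splice_motifs(
    make_call("A", "B", "chrP", 6, "+", "chrP", 7, "+"), genome)$acceptor_motif)
  ## the same context on the reverse complement, minus strand
  posm <- nchar(chr) + 1 - 6
  expect_true(splice_motifs(
    make_call("A", "B", "chrM", posm, "-", "chrP", 7, "+"), genome)$donor_motif)
  ## contig edge -> NA
  edge <- splice_motifs(make_call("A", "B", "chrP", 1, "+", "chrP", 6, "+"),
                        genome)
  expect_true(is.na(edge$donor_motif))
})

test_that("splice_motifs agrees with a string-slicing oracle on random loci", {
  set.seed(99)
  chr <- rand_dna(3000)
  genome <- c(c1 = chr)
  for (i in 1:1000) {
    pos5 <- sample(10:2990, 1); pos3 <- sample(10:2990, 1)
    s5 <- sample(c("+", "-"), 1); s3 <- sample(c("+", "-"), 1)
    m <- splice_motifs(make_call("A", "B", "c1", pos5, s5, "c1", pos3, s3),
                       genome)
    don_ctx <- if (s5 == "+") substr(chr, pos5 - 1, pos5 + 2)
               else revcomp(substr(chr, pos5 - 2, pos5 + 1))
    acc_ctx <- if (s3 == "+") substr(chr, pos3 - 2, pos3)
               else revcomp(substr(chr, pos3, pos3 + 2))
    expect_identical(m$donor_motif, don_ctx == "AGGT" ||
                       (substr(don_ctx, 1, 2) == "AG" & substr(don_ctx, 3, 4) == "GT"))
    expect_identical(m$acceptor_motif, substr(acc_ctx, 1, 2) == "AG" &&
                       substr(acc_ctx, 3, 3) == "G")
  }
})

test_that("isoform naming uses exon ordinals and breaks ties to the longest transcript", {
  ## 14-exon 5' gene; break at the end of exon 14 joined to exon 2 start
  starts <- seq(1001, by = 500, length.out = 14)
  ann <- build_annotation(rbind(
    gene_features("BCRish", "chr22", "+", iv(starts, starts + 99)),
    gene_features("ABLish", "chr9", "+", iv(c(501, 901, 1301), c(600, 1000, 1400)))
  ))
  call <- make_call("BCRish", "ABLish", "chr22", starts[14] + 99, "+",
                    "chr9", 901, "+")
  expect_equal(isoform_name(call, ann), "e14e2")
  call2 <- make_call("BCRish", "ABLish", "chr22", starts[1] + 99, "+",
                     "chr9", 901, "+")
  expect_equal(isoform_name(call2, ann), "e1e2")

  ## two transcripts agree on the boundary; the longer one is used, and the
  ## choice is deterministic
  feats <- rbind(
    gene_features("GX", "chr1", "+", iv(c(101, 301), c(200, 400)),
                  transcript_id = "short"),
    gene_features("GX", "chr1", "+", iv(c(1, 101, 301), c(80, 200, 400)),
                  transcript_id = "long"),
    gene_features("GY", "chr2", "+", iv(c(11, 111), c(60, 160)))
  )
  ann2 <- build_annotation(feats)
  call3 <- make_call("GX", "GY", "chr1", 200, "+", "chr2", 111, "+")
  expect_equal(isoform_name(call3, ann2), "e2e2")   # exon 2 of "long"
  expect_identical(isoform_name(call3, ann2), isoform_name(call3, ann2))
  ## intronic breakpoint is unnamed
  expect_true(is.na(isoform_name(
    make_call("GX", "GY", "chr1", 250, "+", "chr2", 111, "+"), ann2)))
})
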