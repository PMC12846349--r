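# build a plus-strand record whose single ORF ends ...GTTTTT <spacer> TAA,
# followed by an arbitrary downstream tail (all in coding orientation)
toy_locus_record <- function(orf_body_codons = 10, spacer_codons = 0,
                             tail = "", id = "toy") {
  orf <- paste0("ATG", strrep("AAA", orf_body_codons), "GTTTTT",
                strrep("CAA", spacer_codons), "TAA")
  feats <- data.frame(feature_id = "orf1", start = 0L,
                      end = nchar(orf), strand = "+", kind = "CDS",
                      stringsAsFactors = FALSE)
  genome_record(id, paste0(orf, tail), feats)
}

test_that("find_slippery locates the motif and its offset from the stop", {
  rec <- toy_locus_record()     # ORF ends ...GTTTTTTAA
  orf <- rec$features[1, ]
  sites <- find_slippery(rec, orf)
  expect_length(sites, 1L)
  # motif start is 9 nt before the ORF end, 6 nt before the stop start
  expect_equal(sites[[1]]$offset_from_stop, 6L)
  expect_equal(sites[[1]]$genome_pos, orf$end - 9L)
  expect_equal(sites[[1]]$motif, "GTTTTT")
})

test_that("find_slippery respects the 3' search window", {
  # motif ~200 nt upstream of the stop is outside the default 60 nt window
  orf <- paste0("ATG", "GTTTTT", strrep("AAA", 70), "TAA")
  rec <- genome_record("far", orf,
                       data.frame(feature_id = "orf1", start = 0L,
                                  end = nchar(orf), strand = "+",
                                  kind = "CDS"))
  expect_length(find_slippery(rec, rec$features[1, ]), 0L)
  # widening the window to the whole ORF recovers it
  expect_length(find_slippery(rec, rec$features[1, ],
                              window_nt = nchar(orf)), 1L)
  # and an ORF with no motif at all yields an empty list
  orf2 <- paste0("ATG", strrep("AAA", 20), "TAA")
  rec2 <- genome_record("none", orf2,
                        data.frame(feature_id = "orf1", start = 0L,
                                   end = nchar(orf2), strand = "+",
                                   kind = "CDS"))
  expect_length(find_slippery(rec2, rec2$features[1, ]), 0L)
})

test_that("minus1_extension measures a hand-built stop-free extension", {
  # after the slip the -1 frame reads TTA ACC ACC ...; the CC shim puts
  # the closing TAA on the -1 frame, 107 nt past the frame-0 stop start
  rec <- toy_locus_record(tail = paste0(strrep("CCA", 33), "CC", "TAA"))
  orf <- rec$features[1, ]
  site <- find_slippery(rec, orf)[[1]]
  res <- minus1_extension(rec, orf, site)
  oracle <- oracle_minus1(rec$sequence, orf$end, site$local_pos)
  expect_false(res$premature_stop)
  expect_false(res$unterminated)
  expect_equal(res$extension_nt, 107L)
  expect_equal(res$extension_nt, oracle$extension)
  # no -1 stop within the scan limit: flagged unterminated, fails
  rec2 <- toy_locus_record(tail = strrep("CCA", 40))
  res2 <- minus1_extension(rec2, rec2$features[1, ],
                           find_slippery(rec2, rec2$features[1, ])[[1]],
                           scan_limit_nt = 120)
  expect_true(res2$unterminated)
  expect_false(res2$passes)
  expect_error(minus1_extension(rec, orf, NULL), "absent")
})

test_that("scanner decisions match the codon-walk oracle on random loci", {
  withr::local_seed(57)
  for (i in 1:30) {
    tail <- random_dna(3 * sample(20:80, 1))
    rec <- toy_locus_record(orf_body_codons = sample(5:30, 1),
                            spacer_codons = sample(0:10, 1), tail = tail)
    orf <- rec$features[1, ]
    site <- find_slippery(rec, orf)[[1]]
    res <- minus1_extension(rec, orf, site, scan_limit_nt = nchar(tail))
    oracle <- oracle_minus1(rec$sequence, orf$end, site$local_pos)
    expect_equal(res$premature_stop, oracle$premature)
    expect_equal(res$unterminated, oracle$unterminated)
    if (!oracle$premature && !oracle$unterminated)
      expect_equal(res$extension_nt, oracle$extension)
  }
})

test_that("allele deduplication is case-insensitive and count-conserving", {
  d <- dedupe_alleles(c("ACGT", "acgt", "TTTT"))
  expect_equal(d$allele, c("ACGT", "TTTT"))
  expect_equal(d$count, c(2L, 1L))
  d1 <- dedupe_alleles("ACGT")
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$count, 1L)
  expect_error(dedupe_alleles(character(0)), "empty")
  withr::local_seed(61)
  for (i in 1:10) {
    x <- sample(c("AA", "CC", "GG", "TT"), sample(5:50, 1), replace = TRUE)
    d <- dedupe_alleles(x)
    expect_equal(sum(d$count), length(x))
    expect_true(all(diff(d$count) <= 0))
  }
})

test_that("survey_locus reproduces generator ground truth with negatives", {
  neg <- rep("none", 20)
  neg[c(4, 11, 17)] <- "scramble_motif"
  neg[c(7, 19)] <- "plant_minus1_stop"
  gp <- make_prf_genomes(20, negatives = neg, seed = 301,
                         strand = rep(c("+", "-"), 10))
  lm <- setNames(rep("tac_orf", 20),
                 vapply(gp$genomes, `[[`, character(1), "id"))
  sv <- survey_locus(gp$genomes, lm)
  expect_equal(sv$per_genome$passes, gp$truth$expected_pass)
  expect_equal(sv$per_genome$site_found, gp$truth$expected_site)
  expect_equal(sv$per_genome$premature_stop, gp$truth$expected_premature)
  pos <- gp$truth$negative == "none"
  expect_equal(sv$per_genome$extension_nt[pos], gp$truth$extension_nt[pos])
  expect_equal(sv$n_genomes, 20L)
  expect_lte(sv$n_unique_alleles, 20L)
})

test_that("the motif columns are invariant in the allele alignment", {
  gp <- make_prf_genomes(15, divergence = 0.05, seed = 97)
  lm <- setNames(rep("tac_orf", 15),
                 vapply(gp$genomes, `[[`, character(1), "id"))
  sv <- survey_locus(gp$genomes, lm)
  expect_true(all(sv$per_genome$passes))
  expect_gt(sv$n_unique_alleles, 1L)  # 5% divergence: alleles differ
  # the string of invariant-column symbols must contain the intact motif
  mat <- do.call(rbind, strsplit(sv$msa$rows, ""))
  inv <- apply(mat, 2, function(col)
    !any(col == "-") && length(unique(col)) == 1L)
  inv_string <- paste(mat[1, inv], collapse = "")
  expect_match(inv_string, "GTTTTT")
})

test_that("extension is invariant under strand placement of the locus", {
  for (seed in c(5, 6)) {
    gp_p <- make_prf_genomes(3, seed = seed, strand = "+")
    gp_m <- make_prf_genomes(3, seed = seed, strand = "-")
    lm <- setNames(rep("tac_orf", 3), sprintf("g%03d", 1:3))
    sv_p <- survey_locus(gp_p$genomes, lm)
    sv_m <- survey_locus(gp_m$genomes, lm)
    expect_equal(sv_p$per_genome$extension_nt, sv_m$per_genome$extension_nt)
    expect_equal(sv_p$per_genome$passes, sv_m$per_genome$passes)
  }
})

test_that("a missing ORF mapping names the offending genome", {
  gp <- make_prf_genomes(2, seed = 8)
  lm <- c(g001 = "tac_orf", g002 = "wrong_id")
  expect_error(survey_locus(gp$genomes, lm), "g002")
  expect_error(survey_locus(gp$genomes, c(g001 = "tac_orf")), "g002")
})
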