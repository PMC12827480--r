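test_that("conversion ratios follow the strand-specific formulas", {
  pl <- data.frame(contig = "c1", pos = c(10L, 20L, 30L),
                   strand = c("+", "-", "+"),
                   countA = c(9L, 0L, 0L), countC = c(0L, 17L, 0L),
                   countG = c(1L, 0L, 0L), countT = c(0L, 3L, 0L))
  rt <- conversion_ratio(pl)
  expect_equal(rt$ratio[1], 0.9)        # A/(A+G) forward
  expect_equal(rt$depth_rel[1], 10)
  expect_equal(rt$ratio[2], 0.15)       # T/(T+C) reverse
  expect_equal(rt$depth_rel[2], 20)
  expect_true(is.na(rt$ratio[3]))       # zero relevant depth: undefined
  expect_false(rt$defined[3])
  # undefined rows are never called
  expect_equal(nrow(call_glori_sites(rt, min_depth = 0, min_ratio = 0)), 2L)
})

test_that("rows with the wrong reference base are rejected", {
  seqs <- c(c1 = "CCACC")   # only position 2 is an A on the forward strand
  pl <- data.frame(contig = "c1", pos = c(2L, 3L), strand = "+",
                   countA = 5L, countC = 0L, countG = 5L, countT = 0L)
  rt <- conversion_ratio(pl, seqs)
  expect_equal(nrow(rt), 1L)
  expect_equal(attr(rt, "n_rejected"), 1L)
  expect_equal(rt$pos, 2L)
})

test_that("site calling applies inclusive boundaries", {
  mk <- function(A, G) {
    conversion_ratio(data.frame(contig = "c1", pos = 1L, strand = "+",
                                countA = A, countC = 0L, countG = G,
                                countT = 0L))
  }
  expect_equal(nrow(call_glori_sites(mk(2L, 13L))), 1L)   # depth 15, ratio 2/15 >= 0.1
  expect_equal(nrow(call_glori_sites(mk(13L, 1L))), 0L)   # depth 14 despite ratio 0.93
  # exact boundary: depth 20, ratio exactly 0.1
  expect_equal(nrow(call_glori_sites(mk(2L, 18L))), 1L)
  # just below the ratio boundary
  expect_equal(nrow(call_glori_sites(mk(1L, 18L))), 0L)
})

test_that("site calling equals a brute-force filter on 10,000 rows", {
  set.seed(9)
  n <- 10000
  pl <- data.frame(contig = "c1", pos = seq_len(n),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   countA = rpois(n, 8), countC = rpois(n, 8),
                   countG = rpois(n, 8), countT = rpois(n, 8))
  rt <- conversion_ratio(pl)
  called <- call_glori_sites(rt)
  fwd <- rt$strand == "+"
  depth <- ifelse(fwd, rt$countA + rt$countG, rt$countT + rt$countC)
  ratio <- ifelse(fwd, rt$countA, rt$countT) / depth
  brute <- which(depth >= 15 & !is.na(ratio) & ratio >= 0.1)
  expect_equal(which(rownames(rt) %in% rownames(called)), brute)
  # monotone: raising either threshold never adds sites
  expect_lte(nrow(call_glori_sites(rt, 20, 0.1)), nrow(called))
  expect_lte(nrow(call_glori_sites(rt, 15, 0.2)), nrow(called))
})

test_that("annotation assigns motif context, region class and gene distance", {
  #               0123456789012345
  seqs <- c(c1 = "CCGACTCCGAACTCCC")
  ann <- as_annotation(data.frame(
    gene = "g1", transcript = "t1", region = c("5UTR", "CDS", "3UTR"),
    contig = "c1", start = c(0L, 4L, 8L), end = c(4L, 8L, 16L),
    strand = "+", module = "none"))
  mk_site <- function(pos) {
    conversion_ratio(data.frame(contig = "c1", pos = pos, strand = "+",
                                countA = 10L, countC = 0L, countG = 5L,
                                countT = 0L))
  }
  s1 <- annotate_glori_sites(mk_site(3L), ann, seqs)   # GAC context, 5UTR
  expect_equal(s1$motif, "GAC")
  expect_equal(s1$region_class, "5UTR")
  s2 <- annotate_glori_sites(mk_site(10L), ann, seqs)  # GAAC second A, 3UTR
  expect_equal(s2$motif, "GAAC")
  expect_equal(s2$region_class, "3UTR")

  # a site far from any gene is dropped
  seqs2 <- c(c1 = paste0(strrep("C", 5000), "A", strrep("C", 200)))
  ann2 <- as_annotation(data.frame(
    gene = "g1", transcript = "t1", region = c("5UTR", "CDS", "3UTR"),
    contig = "c1", start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
    strand = "+", module = "none"))
  far <- annotate_glori_sites(mk_site(5000L), ann2, seqs2)
  expect_equal(nrow(far), 0L)
  expect_equal(attr(far, "n_dropped"), 1L)

  # duplicate (position, strand) collapses via the unique position id
  dup <- rbind(mk_site(3L), mk_site(3L))
  expect_equal(nrow(annotate_glori_sites(dup, ann, seqs)), 1L)
})

test_that("GAAC annotation respects the minus strand", {
  # minus-strand GAAC reads on the plus strand as GTTC; site base is T at
  # the position pairing with the second A
  seqs <- c(c1 = "CCGTTCCC")
  ann <- as_annotation(data.frame(
    gene = "g1", transcript = "t1", region = c("3UTR", "CDS", "5UTR"),
    contig = "c1", start = c(0L, 3L, 6L), end = c(3L, 6L, 8L),
    strand = "-", module = "none"))
  pl <- conversion_ratio(data.frame(contig = "c1", pos = 3L, strand = "-",
                                    countA = 0L, countC = 5L, countG = 0L,
                                    countT = 10L))
  s <- annotate_glori_sites(pl, ann, seqs)
  expect_equal(s$motif, "GAAC")
})

test_that("conversion metagene recovers a planted +2 peak and the inhibitor effect", {
  sim <- small_sim()
  gl <- simulate_glori(sim, depth_mean = 60, mettl3i_factor = 0.3,
                       replicates = 2, seed = 13)
  called <- list()
  for (nm in names(gl)) {
    meta <- attr(gl[[nm]], "meta")
    if (meta$state != "Day5") next
    sites <- call_glori_sites(conversion_ratio(gl[[nm]], sim$sequences))
    sites$condition <- meta$condition
    sites$replicate <- meta$replicate
    called[[nm]] <- sites
  }
  called <- do.call(rbind, called)
  # centres: planted composite AREs (paired ARE centres of methylated sites)
  st <- sim$manifest$sites
  comp_are <- st[st$motif_class == "WWAWW" & !is.na(st$d_planted), ]
  centres <- data.frame(contig = comp_are$contig, centre = comp_are$centre,
                        strand = comp_are$strand)
  prof <- glori_metagene(called, centres, flank = 10,
                         conditions = c("DMSO", "METTL3i"))
  dmso <- prof[prof$condition == "DMSO", ]
  # planted pair distances are weighted toward +2: the profile mode sits at
  # small positive offsets and dwarfs the upstream side
  expect_equal(dmso$offset[which.max(dmso$value)], 2)
  m3i <- prof[prof$condition == "METTL3i", ]
  ratio <- sum(m3i$value) / sum(dmso$value)
  expect_gt(ratio, 0.15)
  expect_lt(ratio, 0.45)
  expect_error(glori_metagene(called, centres, conditions = "Mock"),
               "available")
})

test_that("the within-window count fraction matches an overlap oracle", {
  set.seed(3)
  sites <- data.frame(contig = "c1", pos = sample(0:999, 80), strand = "+",
                      countA = rpois(80, 20), countC = 0L, countG = 0L,
                      countT = 0L)
  refs <- data.frame(contig = "c1", centre = sample(0:999, 15), strand = "+")
  f <- fraction_near_sites(sites, refs, window = 4)
  near <- vapply(sites$pos, function(p) any(abs(refs$centre - p) <= 4),
                 logical(1))
  expect_equal(f, sum(sites$countA[near]) / sum(sites$countA))
})
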