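test_that("thresholding keeps in-peak positions above the region quantile", {
  tr <- crosslink_track(data.frame(
    contig = "c1", pos = c(10L, 20L, 30L, 40L), strand = "+",
    count = c(1L, 1L, 1L, 10L)))
  peaks <- data.frame(contig = "c1", start = 38L, end = 43L, strand = "+")
  th <- threshold_crosslinks(tr, peaks, percentile = 0.7)
  # quantile 0.7 of {1,1,1,10} (inverse ECDF) is 1: every in-peak position
  # qualifies, and only the count-10 position is in-peak
  expect_equal(th$thresholded$pos, 40L)
  expect_setequal(th$background$pos, c(10L, 20L, 30L))

  expect_warning(th0 <- threshold_crosslinks(tr, peaks[0, ]), "no peaks")
  expect_equal(nrow(th0$thresholded), 0L)
  expect_equal(nrow(th0$background), 4L)
})

test_that("thresholding equals a brute-force oracle and is monotone", {
  set.seed(21)
  ev <- data.frame(contig = "c1", pos = sort(sample(0:2000, 300)),
                   strand = "+",
                   count = rpois(300, 2) + 1L)
  tr <- crosslink_track(ev)
  peaks <- data.frame(contig = "c1", start = c(100L, 900L),
                      end = c(400L, 1500L), strand = "+")
  regions <- data.frame(contig = "c1", start = 0L, end = 2001L, strand = "+")
  prev <- Inf
  for (p in c(0.3, 0.5, 0.7, 0.9)) {
    th <- threshold_crosslinks(tr, peaks, regions, percentile = p)
    q <- quantile(ev$count, p, type = 1, names = FALSE)
    in_peak <- (ev$pos >= 100 & ev$pos < 400) | (ev$pos >= 900 & ev$pos < 1500)
    expect_setequal(th$thresholded$pos, ev$pos[in_peak & ev$count >= q])
    expect_setequal(th$background$pos, ev$pos[!in_peak])
    expect_lte(nrow(th$thresholded), prev)  # raising p never enlarges
    prev <- nrow(th$thresholded)
  }
})

test_that("k-mer scores find a k-mer planted around thresholded sites", {
  set.seed(31)
  L <- 60000
  seqs <- c(c1 = random_dna(L))
  thr_pos <- sort(sample(seq(200, L - 200, by = 37), 300))
  bg_pos <- setdiff(sort(sample(200:(L - 200), 3000)), thr_pos)
  # plant CCGTA right at 80% of thresholded sites, 10% of background
  chars <- strsplit(seqs[["c1"]], "")[[1]]
  for (p in thr_pos[runif(300) < 0.8]) chars[(p + 1):(p + 5)] <- c("C", "C", "G", "T", "A")
  for (p in sample(bg_pos, 300)) chars[(p + 1):(p + 5)] <- c("C", "C", "G", "T", "A")
  seqs[["c1"]] <- paste0(chars, collapse = "")
  thr <- data.frame(contig = "c1", pos = thr_pos, strand = "+", count = 2L)
  bg <- data.frame(contig = "c1", pos = bg_pos, strand = "+", count = 1L)
  pk <- peka_scores(thr, bg, seqs, n_perm = 50, seed = 4)
  expect_equal(pk$scores$kmer[1], "CCGTA")
  # determinism and order invariance
  pk2 <- peka_scores(thr[sample(nrow(thr)), ], bg, seqs, n_perm = 50,
                     seed = 4)
  expect_equal(pk2$scores, pk$scores)
})

test_that("k-mer scores refuse unstable inputs", {
  seqs <- c(c1 = random_dna(1000, seed = 1))
  thr <- data.frame(contig = "c1", pos = 500:504, strand = "+", count = 1L)
  bg <- data.frame(contig = "c1", pos = 100:400, strand = "+", count = 1L)
  expect_error(peka_scores(thr, bg, seqs, n_perm = 5, seed = 1),
               "fewer than 10")
})

test_that("metagene profiles align, normalise per UTR and respect strand", {
  tr <- crosslink_track(data.frame(contig = "c1", pos = 100L, strand = "+",
                                   count = 1L))
  centres <- data.frame(contig = "c1", centre = 100L, strand = "+")
  prof <- metagene_profile(tr, centres, flank = 5)
  expect_equal(prof$value[prof$offset == 0], 1)
  expect_equal(sum(prof$value), 1)

  # a minus-strand centre sees genomic downstream as negative offsets
  trm <- crosslink_track(data.frame(contig = "c1", pos = 102L, strand = "-",
                                    count = 3L))
  cm <- data.frame(contig = "c1", centre = 100L, strand = "-")
  pm <- metagene_profile(trm, cm, flank = 5)
  expect_equal(pm$value[pm$offset == -2], 3)

  # flipping the strand of all inputs leaves the profile unchanged
  set.seed(5)
  ev <- data.frame(contig = "c1", pos = sample(50:150, 40), strand = "+",
                   count = sample(1:5, 40, replace = TRUE))
  cen <- data.frame(contig = "c1", centre = c(80L, 120L), strand = "+")
  p1 <- metagene_profile(crosslink_track(ev), cen, flank = 10)
  ev2 <- transform(ev, strand = "-")
  cen2 <- transform(cen, strand = "-")
  p2 <- metagene_profile(crosslink_track(ev2), cen2, flank = 10)
  expect_equal(p2$value, rev(p1$value))
})

test_that("a uniform track gives a flat metagene profile", {
  set.seed(6)
  cnt <- as.vector(rmultinom(1, 10000, rep(1, 200)))
  tr <- crosslink_track(data.frame(contig = "c1", pos = 0:199, strand = "+",
                                   count = cnt))
  cen <- data.frame(contig = "c1", centre = seq(50L, 150L, by = 2L),
                    strand = "+")
  prof <- metagene_profile(tr, cen, flank = 20)
  expect_lt(max(prof$value) / min(prof$value), 1.2)
})

test_that("scaled region density sums to one and localises planted signal", {
  sim <- small_sim()
  utrs <- annotation_regions(sim$annotation, "3UTR")
  # all events in the first decile of 3'UTRs (transcript orientation)
  ev <- do.call(rbind, lapply(seq_len(10), function(i) {
    u <- utrs[i, ]
    off <- seq_len(max(2L, (u$end - u$start) %/% 12L))
    data.frame(contig = u$contig,
               pos = metadecay:::tx_to_genomic(off, u$start, u$end, u$strand),
               strand = u$strand, count = 1L)
  }))
  tr <- crosslink_track(ev)
  dens <- scaled_region_density(tr, sim$annotation, bins_per_region = 10)
  expect_equal(sum(dens$density), 1, tolerance = 1e-9)
  u3 <- dens[dens$region == "3UTR", ]
  expect_gt(sum(u3$density[u3$bin <= 2]), 0.95)
  expect_equal(sum(dens$density[dens$region != "3UTR"]), 0)
})

test_that("substitution profiles tally planted signals by type and offset", {
  sites <- data.frame(contig = "c1", centre = c(100L, 200L), strand = "+")
  subs <- data.frame(contig = "c1", pos = c(101L, 201L, 150L),
                     strand = "+", from = c("C", "C", "T"),
                     to = c("T", "T", "A"),
                     sub_count = c(5L, 10L, 4L), depth = c(10L, 20L, 8L))
  prof <- cims_profile(subs, sites, flank = 5)
  ct <- prof[prof$type == "C>T", ]
  expect_equal(ct$rate[ct$offset == 1], 0.5)   # mean(5/10, 10/20)
  expect_equal(sum(ct$rate[ct$offset != 1]), 0)
  ta <- prof[prof$type == "T>A", ]
  expect_equal(sum(ta$rate), 0)                # T>A at 150 is outside windows

  none <- cims_profile(subs[0, ], sites, flank = 5)
  expect_equal(sum(none$rate), 0)
  expect_error(cims_profile(subs, sites, types = "G>C"), "must be one of")
})

test_that("substitution profiles equal a direct tally on a 50-site fixture", {
  set.seed(77)
  sites <- data.frame(contig = "c1",
                      centre = sort(sample(seq(100, 5000, 60), 50)),
                      strand = "+")
  subs <- data.frame(contig = "c1", pos = sample(0:5100, 400),
                     strand = "+",
                     from = sample(c("C", "T", "A"), 400, replace = TRUE),
                     to = NA)
  subs$to <- c(C = "T", T = "A", A = "T")[subs$from]
  subs$depth <- sample(5:30, 400, replace = TRUE)
  subs$sub_count <- rbinom(400, subs$depth, 0.2)
  flank <- 7
  prof <- cims_profile(subs, sites, flank = flank)
  for (ty in c("C>T", "T>A", "A>T")) {
    rec <- subs[paste0(subs$from, ">", subs$to) == ty, ]
    for (off in c(-7, 0, 3, 7)) {
      rates <- vapply(sites$centre, function(cc) {
        r <- rec[rec$pos == cc + off, ]
        if (nrow(r) == 0) 0 else r$sub_count[1] / r$depth[1]
      }, numeric(1))
      expect_equal(prof$rate[prof$type == ty & prof$offset == off],
                   mean(rates))
    }
  }
})
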