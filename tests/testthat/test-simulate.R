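test_that("the generator is seed-deterministic down to the FASTA bytes", {
  s1 <- generate_transcriptome(40, seed = 5)
  s2 <- generate_transcriptome(40, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(s1$sequences, f1)
  write_fasta(s2$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(s1$manifest$genes, s2$manifest$genes)
  expect_error(generate_transcriptome(10, seed = 1), "at least 40")
  expect_error(generate_transcriptome(40, archetype_mix = c(1, 1, 0, 0)),
               "sum to 1")
})

test_that("a composite-only mix plants at least one pair per gene", {
  sim <- generate_transcriptome(40, archetype_mix = c(0, 1, 0, 0), seed = 6)
  st <- sim$manifest$sites
  per_gene <- table(st$gene[st$methylated])
  expect_equal(sort(names(per_gene)), sort(sim$manifest$genes$gene))
  expect_true(all(per_gene >= 1))
  expect_true(all(sim$manifest$genes$archetype == "composite"))
  # paired plants record their centre distance
  expect_true(all(!is.na(st$d_planted)))
})

test_that("scanning the generated sequences recovers every planted site", {
  sim <- small_sim()
  st <- sim$manifest$sites
  utrs <- annotation_regions(sim$annotation, "3UTR")
  for (cl in c("RRACH", "WWAWW")) {
    found <- motif_sites_in_3utrs(sim$annotation, sim$sequences, cl)
    planted <- st[st$motif_class == cl, ]
    expect_true(all(paste(planted$contig, planted$centre) %in%
                      paste(found$contig, found$centre)))
    expect_gte(nrow(found), nrow(planted))  # chance occurrences allowed
  }
})

test_that("crosslink enrichment is absent at fold 1 equivalents and present when planted", {
  sim <- small_sim()
  # input tracks follow the background-only model: the planted-proximal
  # event fraction matches the proximal length fraction
  xl <- simulate_crosslinks(sim, enrichment_fold = 8, n_events = 5e4,
                            n_miclip_per_state = 1, n_input_per_state = 1,
                            seed = 31)
  st <- sim$manifest$sites
  utrs <- annotation_regions(sim$annotation, "3UTR")
  utr_len <- sum(utrs$end - utrs$start)
  prox_len <- nrow(st) * 5  # +/-2 around each planted centre
  input_tracks <- xl$tracks[grepl("^input", names(xl$tracks))]
  ev <- do.call(rbind, lapply(input_tracks, function(t) t$events))
  near <- rep(FALSE, nrow(ev))
  key <- paste(ev$contig, ev$pos)
  for (d in -2:2) near <- near | key %in% paste(st$contig, st$centre + d)
  frac <- sum(ev$count[near]) / sum(ev$count)
  # expression weighting makes this only approximately the length fraction;
  # it must stay far below the signal-track enrichment
  expect_lt(frac, 3 * prox_len / utr_len)

  mi <- xl$tracks[[grep("^miCLIP", names(xl$tracks))[1]]]$events
  near_mi <- rep(FALSE, nrow(mi))
  key_mi <- paste(mi$contig, mi$pos)
  for (d in -2:2) near_mi <- near_mi | key_mi %in% paste(st$contig, st$centre + d)
  expect_gt(sum(mi$count[near_mi]) / sum(mi$count), 2 * frac)
})

test_that("planted k-mers dominate the enrichment scores end to end", {
  sim <- generate_transcriptome(60, archetype_mix = c(0, 0, 1, 0), seed = 8)
  xl <- simulate_crosslinks(sim, enrichment_fold = 20, n_events = 1e5,
                            n_miclip_per_state = 1, n_input_per_state = 1,
                            seed = 9)
  tr <- xl$tracks[[grep("^miCLIP", names(xl$tracks))[1]]]
  th <- threshold_crosslinks(tr, xl$peaks)
  pk <- peka_scores(th$thresholded, th$background, sim$sequences,
                    n_perm = 40, seed = 10)
  top <- pk$scores$kmer[1:20]
  is_rrach <- vapply(top, function(k) nrow(scan_pentamers(k, "RRACH")) == 1,
                     logical(1))
  expect_gte(sum(is_rrach), 5)
})

test_that("conversion pileups concentrate called signal at composite AREs", {
  sim <- generate_transcriptome(60, archetype_mix = c(0, 1, 0, 0), seed = 12)
  gl <- simulate_glori(sim, depth_mean = 60, replicates = 1, seed = 13)
  pl <- gl[["Day5.DMSO.r1"]]
  called <- call_glori_sites(conversion_ratio(pl, sim$sequences))
  st <- sim$manifest$sites
  ares <- st[st$motif_class == "WWAWW", ]
  frac <- fraction_near_sites(called, data.frame(
    contig = ares$contig, centre = ares$centre, strand = ares$strand),
    window = 4)
  # called counts sit within +/-4 nt of planted AREs far above the length
  # fraction of those windows
  utrs <- annotation_regions(sim$annotation, "3UTR")
  chance <- nrow(ares) * 9 / sum(utrs$end - utrs$start)
  expect_gt(frac, 5 * chance)
})

test_that("an inert inhibitor leaves the conditions indistinguishable", {
  sim <- small_sim()
  gl <- simulate_glori(sim, mettl3i_factor = 1, replicates = 1, seed = 14)
  ok <- 0; n_runs <- 0
  for (state in c("noAct", "Day1", "Day5")) {
    a <- gl[[paste0(state, ".DMSO.r1")]]
    b <- gl[[paste0(state, ".METTL3i.r1")]]
    ra <- conversion_ratio(a, sim$sequences)
    rb <- conversion_ratio(b, sim$sequences)
    ca <- call_glori_sites(ra); cb <- call_glori_sites(rb)
    n_runs <- n_runs + 1
    p <- suppressWarnings(ks.test(ca$ratio, cb$ratio))$p.value
    if (p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, n_runs - 1)
})

test_that("binomial conversion concentrates near the planted level", {
  sim <- generate_transcriptome(80, archetype_mix = c(0, 1, 0, 0), seed = 15)
  gl <- simulate_glori(sim, depth_mean = 100,
                       conversion_by_class = c(composite = 0.5,
                                               isolated = 0.5),
                       state_factor = c(Day5 = 1), replicates = 1,
                       seed = 16)
  pl <- gl[["Day5.DMSO.r1"]]
  called <- call_glori_sites(conversion_ratio(pl, sim$sequences))
  st <- sim$manifest$sites
  meth_key <- paste(st$contig[st$methylated], st$centre[st$methylated])
  planted <- called[paste(called$contig, called$pos) %in% meth_key, ]
  expect_gt(mean(abs(planted$ratio - 0.5) <= 0.1), 0.95)
})

test_that("noiseless time courses reproduce the planted half-lives", {
  sim <- small_sim()
  sl <- simulate_slam(sim, noise_cv = 0, sdlog = 0, seed = 17)
  day5 <- sl$curves[sl$curves$state == "Day5", ]
  est <- fit_decay_table(day5[, c("transcript", "time_h", "rate")],
                         background = sl$background)
  truth <- sl$truth[sl$truth$state == "Day5", ]
  m <- merge(est, truth, by = "transcript")
  rel <- abs(m$t_half - m$t_half_true) / m$t_half_true
  expect_lt(max(rel[m$reliable]), 1e-3)
})

test_that("state-wise planted medians follow the half-life map ordering", {
  sim <- small_sim(n_genes = 120)
  sl <- simulate_slam(sim, seed = 18)
  med <- tapply(sl$truth$t_half_true, sl$truth$state, median)
  expect_lt(med[["Day5"]], med[["Day1"]])
  expect_lt(med[["Day1"]], med[["noAct"]])
  by_class <- tapply(sl$truth$t_half_true[sl$truth$state == "Day5"],
                     sl$truth$site_class[sl$truth$state == "Day5"], median)
  expect_lt(by_class[["composite"]], by_class[["isolated"]])
  expect_lt(by_class[["isolated"]], by_class[["none"]])
  expect_error(simulate_slam(sim, t_half_by_class = list(
    Day5 = c(composite = -1, isolated = 2, none = 3))), "positive")
})

test_that("module informativeness moves labels from independent to deterministic", {
  sim <- small_sim(n_genes = 120)
  comp <- sim$manifest$genes$archetype == "composite"
  # informativeness 0: composite genes land in C/D/F at the same rate as
  # the rest (chi-squared independence over repeated draws)
  ok_null <- 0
  for (s in 1:10) {
    mod0 <- assign_modules(sim, informativeness = 0, seed = s)
    in_short <- mod0[sim$manifest$genes$gene] %in% c("C", "D", "F")
    p <- suppressWarnings(chisq.test(table(comp, in_short))$p.value)
    if (p > 0.05) ok_null <- ok_null + 1
  }
  expect_gte(ok_null, 8)
  mod1 <- assign_modules(sim, informativeness = 1, seed = 3)
  expect_true(all(mod1[sim$manifest$genes$gene[comp]] %in% c("C", "D", "F")))
})
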