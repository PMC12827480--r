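test_that("size factors recover column scalings and match brute force", {
  m <- matrix(rpois(60, 20) + 1L, nrow = 10)
  ident <- cbind(m[, 1], m[, 1], m[, 1])
  f <- size_factors(ident)
  expect_true(all(abs(f / f[1] - 1) < 1e-12))

  scaled <- cbind(a = m[, 1], b = 2L * m[, 1])
  f2 <- size_factors(scaled)
  expect_equal(unname(f2[["b"]] / f2[["a"]]), 2)

  set.seed(18)
  for (i in 1:10) {
    mm <- matrix(rpois(3000, 15), nrow = 500, ncol = 6)
    keep <- apply(mm > 0, 1, all)
    ref <- exp(rowMeans(log(mm[keep, ])))
    brute <- apply(mm[keep, ] / ref, 2, median)
    expect_equal(unname(size_factors(mm)), unname(brute))
  }
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "pseudocount")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(19)
  mm <- matrix(rpois(1200, 25), nrow = 200, ncol = 6)
  expect_equal(unname(size_factors(mm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mm)),
               tolerance = 1e-4)  # DESeq2 interpolates the median in log space
})

test_that("count matrices attribute events to the nearest site per 3'UTR", {
  ann <- as_annotation(data.frame(
    gene = c("g1", "g1", "g1"), transcript = "t1",
    region = c("5UTR", "CDS", "3UTR"), contig = "c1",
    start = c(0L, 100L, 400L), end = c(100L, 400L, 1000L), strand = "+",
    module = "none"))
  sites <- list(
    RRACH = data.frame(contig = "c1", centre = 500L, strand = "+",
                       transcript = "t1"),
    WWAWW = data.frame(contig = "c1", centre = 600L, strand = "+",
                       transcript = "t1"))
  tr <- crosslink_track(data.frame(
    contig = "c1", pos = c(500L, 503L, 598L, 700L), strand = "+",
    count = c(5L, 2L, 3L, 4L)), sample_id = "s1")
  mat <- build_count_matrix(list(s1 = tr), sites, ann, scheme = "miclip")
  expect_equal(mat$counts["t1", "s1.RRACH"], 7L)  # 500 + 503
  expect_equal(mat$counts["t1", "s1.WWAWW"], 3L)  # 598
  expect_equal(mat$n_outside, 1L)                  # 700 is outside windows
})

test_that("count matrices equal an interval-overlap oracle on a fixture", {
  sim <- small_sim()
  ms <- list(
    RRACH = motif_sites_in_3utrs(sim$annotation, sim$sequences, "RRACH"),
    WWAWW = motif_sites_in_3utrs(sim$annotation, sim$sequences, "WWAWW"))
  xl <- simulate_crosslinks(sim, n_events = 2e4, n_miclip_per_state = 1,
                            n_input_per_state = 1, seed = 23)
  tr <- xl$tracks[[1]]
  mat <- suppressMessages(
    build_count_matrix(list(s = tr), ms, sim$annotation, scheme = "miclip"))
  # oracle: per event, nearest centre over both classes within 10 nt
  ev <- tr$events
  oracle <- matrix(0L, nrow(mat$counts), ncol(mat$counts),
                   dimnames = dimnames(mat$counts))
  for (i in seq_len(nrow(ev))) {
    best <- NULL; bd <- Inf
    for (cl in names(ms)) {
      st <- ms[[cl]]
      sel <- st$contig == ev$contig[i] & st$strand == ev$strand[i]
      if (!any(sel)) next
      d <- abs(st$centre[sel] - ev$pos[i])
      j <- which.min(d)
      if (d[j] <= 10 && d[j] < bd) {
        bd <- d[j]; best <- c(cl, st$transcript[sel][j])
      }
    }
    if (!is.null(best)) {
      col <- paste0("s.", best[1])
      oracle[best[2], col] <- oracle[best[2], col] + ev$count[i]
    }
  }
  expect_equal(mat$counts, oracle)
})

test_that("the conversion scheme splits RRACH sites consistently with the composite caller", {
  sim <- small_sim()
  ms <- list(
    RRACH = motif_sites_in_3utrs(sim$annotation, sim$sequences, "RRACH"),
    WWAWW = motif_sites_in_3utrs(sim$annotation, sim$sequences, "WWAWW"))
  tr <- crosslink_track(data.frame(contig = ms$RRACH$contig[1],
                                   pos = ms$RRACH$centre[1],
                                   strand = ms$RRACH$strand[1], count = 1L))
  mat <- build_count_matrix(list(s = tr), ms, sim$annotation,
                            scheme = "glori", composite_window = 50)
  expect_setequal(unique(mat$classes), c("ARE_flanking", "RRACH_only"))
  # cross-module consistency: the partition equals per-transcript composite
  # labels from the motif engine at the same window
  utrs <- annotation_regions(sim$annotation, "3UTR")
  for (txi in sample(nrow(utrs), 10)) {
    u <- utrs[txi, ]
    rr <- ms$RRACH[ms$RRACH$transcript == u$transcript, ]
    are <- ms$WWAWW[ms$WWAWW$transcript == u$transcript, ]
    if (nrow(rr) == 0) next
    flank_engine <- vapply(rr$centre, function(cc) {
      nrow(are) > 0 && min(abs(are$centre - cc)) <= 50
    }, logical(1))
    cc <- call_composites(
      data.frame(centre = rr$tx_centre),
      data.frame(centre = are$tx_centre), window_nt = 50)
    # call_composites is ARE-anchored; check agreement via distances
    for (k in seq_len(nrow(rr))) {
      d_g <- if (nrow(are)) min(abs(are$centre - rr$centre[k])) else Inf
      d_t <- if (nrow(are)) min(abs(are$tx_centre - rr$tx_centre[k])) else Inf
      expect_equal(d_g, d_t)  # genomic and transcript distances agree
      expect_equal(flank_engine[k], d_t <= 50)
    }
  }
})

test_that("low-signal exclusion applies the strict input cutoff and mean flag", {
  counts <- rbind(t1 = c(10L, 10L, 250L, 260L),
                  t2 = c(2L, 2L, 240L, 230L),
                  t3 = c(3L, 1L, 9L, 10L))
  colnames(counts) <- c("m1", "m2", "i1", "i2")
  mat <- structure(list(
    counts = counts,
    samples = c("m1", "m2", "i1", "i2"),
    classes = rep("RRACH", 4),
    roles = c("miCLIP", "miCLIP", "input", "input")),
    class = "motif_count_matrix")
  out <- exclude_low_signal(mat, input_min = 500, nomiclip_max = 2)
  expect_equal(out$dropped_inputs, "i1")      # total 499 < 500 dropped
  expect_true("i2" %in% out$samples)           # total 500 kept
  expect_equal(unname(out$low_signal), c(FALSE, TRUE, TRUE))
  # t2 mean miCLIP count is exactly 2: flagged (inclusive)
})

test_that("normalisation standardises rows and ranks planted variance first", {
  set.seed(20)
  base <- matrix(rpois(600, 50), nrow = 100, ncol = 6)
  rownames(base) <- paste0("t", 1:100)
  hits <- 0
  for (rep in 1:20) {
    m <- matrix(rpois(600, 50), nrow = 100, ncol = 6,
                dimnames = list(paste0("t", 1:100), NULL))
    m[1, 4:6] <- m[1, 4:6] * 10L   # planted 10x between-condition change
    f <- rep(1, 6)
    sel <- normalize_and_select(m, f, top_n = 10)
    if ("t1" %in% rownames(sel$z)) hits <- hits + 1
    expect_true(all(abs(rowMeans(sel$z)) < 1e-9))
    expect_true(all(abs(apply(sel$z, 1, var) - 1) < 1e-9))
  }
  expect_gte(hits, 20 * 0.99 - 1)

  m2 <- matrix(rpois(40, 30), nrow = 10, ncol = 4,
               dimnames = list(paste0("t", 1:10), NULL))
  m2[3, ] <- 7L
  expect_warning(sel2 <- normalize_and_select(m2, rep(1, 4), top_n = 50),
                 "top_n")
  expect_true("t3" %in% sel2$constant_rows)
  expect_false("t3" %in% rownames(sel2$z))
})

test_that("hierarchical clustering recovers separated blobs and handles edge k", {
  set.seed(22)
  z <- rbind(matrix(rnorm(100, 0), 20, 5), matrix(rnorm(100, 8), 20, 5))
  rownames(z) <- paste0("t", 1:40)
  truth <- setNames(rep(c("a", "b"), each = 20), rownames(z))
  cl <- hierarchical_cluster(z, k = 2)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth[cl$transcript]), 1)

  singl <- hierarchical_cluster(z, k = nrow(z))
  expect_equal(length(unique(singl$cluster)), nrow(z))
  expect_error(hierarchical_cluster(z, k = 41), "exceeds")

  # row-order invariance: permuting rows changes nothing after id sort
  perm <- sample(nrow(z))
  cl2 <- hierarchical_cluster(z[perm, ], k = 2)
  m1 <- setNames(cl$cluster, cl$transcript)
  m2 <- setNames(cl2$cluster, cl2$transcript)
  expect_equal(mclust::adjustedRandIndex(m1[names(m2)], m2), 1)
})
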