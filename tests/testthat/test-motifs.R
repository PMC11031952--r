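# A handcrafted attention split around known records, for exercising the
# seed rule and merging without a trained model.
toy_attention <- function(records, dn_sim, dn_co) {
  kmers <- unique(unlist(lapply(records, function(r) {
    r$kmer_occurrences$kmer
  })))
  pos <- records[vapply(records, `[[`, 0L, "label") == 1L]
  ids <- vapply(pos, `[[`, "", "id")
  mk <- function(vals) {
    M <- matrix(NA_real_, length(ids), length(kmers),
                dimnames = list(ids, kmers))
    for (r in pos) {
      occ <- unique(r$kmer_occurrences$kmer)
      M[r$id, occ] <- 0
    }
    for (key in names(vals)) {
      parts <- strsplit(key, ":")[[1]]
      M[parts[1], parts[2]] <- vals[[key]]
    }
    M
  }
  structure(list(dnB1_sim = mk(dn_sim), dnB1_co = mk(dn_co)),
            class = "attention_split")
}

test_that("attention collection splits by label and denoises by background", {
  recs <- random_records(12, 20, lenk = 3, seed = 33)
  graph <- build_het_graph(recs, lenk = 3L)
  model <- train_gat(graph, config = gat_config(epochs = 8, d_k = 5,
                                                lenk = 3, seed = 3))
  att <- collect_attention(model, recs)
  labels <- vapply(recs, `[[`, 0L, "label")
  expect_equal(nrow(att$B1_sim), sum(labels == 1L))
  expect_equal(nrow(att$B0_sim), sum(labels == 0L))
  # backgrounds are plain means over the edge entries of the negatives
  expect_equal(att$background_sim, mean(att$B0_sim, na.rm = TRUE))
  expect_equal(att$background_co, mean(att$B0_co, na.rm = TRUE))
  # denoising is elementwise subtraction on edge cells
  expect_equal(att$dnB1_sim, att$B1_sim - att$background_sim)
  # each coefficient row sums to 1 over its edge support
  expect_equal(unname(rowSums(att$B1_sim, na.rm = TRUE)),
               rep(1, nrow(att$B1_sim)), tolerance = 1e-6)
  # all-positive or all-negative input is rejected
  pos_only <- recs[labels == 1L]
  expect_error(collect_attention(model, pos_only), "negative")
})

test_that("seed rule emits exactly the strict-OR qualifying occurrences", {
  recs <- make_records(c("ACGTA", "TACGG", "GGGGG"), c(1L, 1L, 0L),
                       lenk = 3L)
  att <- toy_attention(
    recs,
    dn_sim = list("s01:ACG" = 0.1, "s01:CGT" = -0.05, "s02:ACG" = 0),
    dn_co = list("s01:CGT" = -0.2, "s02:CGG" = 0.07))
  seeds <- find_kmer_seeds(att, recs)
  # s01: ACG qualifies via sim (0.1 > 0); CGT fails both (OR of negatives)
  # s02: ACG has dn_sim = 0 exactly -> strict > excludes; CGG via co
  expect_equal(seeds$sequence_id, c("s01", "s02"))
  expect_equal(seeds$kmer, c("ACG", "CGG"))
  expect_equal(seeds$offset, c(0L, 2L))

  # exhaustive oracle over every (positive sequence, occurrence)
  brute <- list()
  for (r in recs[1:2]) {
    occ <- r$kmer_occurrences
    for (i in seq_len(nrow(occ))) {
      ds <- att$dnB1_sim[r$id, occ$kmer[i]]
      dc <- att$dnB1_co[r$id, occ$kmer[i]]
      if ((!is.na(ds) && ds > 0) || (!is.na(dc) && dc > 0)) {
        brute[[length(brute) + 1L]] <- c(r$id, occ$kmer[i], occ$offset[i])
      }
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(seeds), nrow(brute))
  expect_equal(seeds$kmer, brute[, 2])
})

test_that("seed chaining joins adjacent offsets above the threshold", {
  # positives engineered so TGA -> GAC adjacency is universal
  recs <- make_records(c("TTGACT", "ATGACA", "CTGACC"), rep(1L, 3),
                       lenk = 3L)
  v <- build_vocab(recs, 3L)
  st <- coexist_stats(v, recs)
  expect_equal(coexist_probability(st, "TGA", "GAC"), 1.0)
  seeds <- data.frame(sequence_id = "s01", kmer = c("TGA", "GAC"),
                      offset = c(1L, 2L), dn_sim = 0.1, dn_co = 0.1)
  cand <- merge_seeds(seeds, st, recs, theta_co = 0.5, lenk = 3L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$width, 4L)
  expect_equal(cand$subsequence, "TGAC")

  # below the threshold the chain breaks into two lenk-wide candidates
  cand2 <- merge_seeds(seeds, st, recs, theta_co = 1.1, lenk = 3L)
  expect_equal(nrow(cand2), 2L)
  expect_equal(cand2$width, c(3L, 3L))

  # offset gaps larger than one always break chains
  seeds3 <- data.frame(sequence_id = "s01", kmer = c("TGA", "ACT"),
                       offset = c(1L, 3L), dn_sim = 0.1, dn_co = 0.1)
  cand3 <- merge_seeds(seeds3, st, recs, theta_co = 0, lenk = 3L)
  expect_equal(nrow(cand3), 2L)
})

test_that("chained candidates match brute-force chain enumeration", {
  set.seed(55)
  recs <- random_records(6, 25, lenk = 3, seed = 55, p_pos = 1)
  v <- build_vocab(recs, 3L)
  st <- coexist_stats(v, recs)
  r <- recs[[1]]
  occ <- r$kmer_occurrences
  take <- sort(sample(nrow(occ), 6))
  seeds <- data.frame(sequence_id = r$id, kmer = occ$kmer[take],
                      offset = occ$offset[take], dn_sim = 1, dn_co = 1)
  theta <- 0.5
  cand <- merge_seeds(seeds, st, recs, theta_co = theta, lenk = 3L)
  # oracle: walk the sorted seeds, breaking whenever the join rule fails
  breaks <- c()
  for (i in 2:nrow(seeds)) {
    ok <- seeds$offset[i] == seeds$offset[i - 1] + 1 &&
      coexist_probability(st, seeds$kmer[i - 1], seeds$kmer[i]) >= theta
    if (!ok) breaks <- c(breaks, i)
  }
  starts <- seeds$offset[c(1, breaks)]
  ends <- seeds$offset[c(breaks - 1, nrow(seeds))] + 3L
  expect_equal(cand$start, starts)
  expect_equal(cand$end, ends)
  # every candidate's subsequence equals the sequence slice
  for (i in seq_len(nrow(cand))) {
    expect_equal(cand$subsequence[i],
                 substr(r$sequence, cand$start[i] + 1, cand$end[i]))
  }
})

test_that("overlap merging unions intervals into disjoint instances", {
  recs <- make_records(paste(rep("ACGTT", 6), collapse = ""), 1L, lenk = 5L)
  cand <- data.frame(sequence_id = "s01", start = c(3L, 6L),
                     end = c(8L, 11L), width = 5L,
                     subsequence = "x", n_seeds = 1L)
  merged <- merge_overlaps(cand, recs)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 3L)
  expect_equal(merged$end, 11L)
  expect_equal(merged$subsequence, substr(recs[[1]]$sequence, 4, 11))

  disj <- data.frame(sequence_id = "s01", start = c(0L, 10L),
                     end = c(5L, 15L), width = 5L, subsequence = "x",
                     n_seeds = 1L)
  expect_equal(nrow(merge_overlaps(disj, recs)), 2L)
})

test_that("overlap merging equals a sweep-line union on random intervals", {
  recs <- make_records(paste(rep("ACGTT", 8), collapse = ""), 1L, lenk = 5L)
  set.seed(66)
  for (rep in 1:5) {
    st <- sample(0:30, 10, replace = TRUE)
    cand <- data.frame(sequence_id = "s01", start = st,
                       end = st + sample(3:8, 10, replace = TRUE),
                       width = 5L, subsequence = "x", n_seeds = 1L)
    merged <- merge_overlaps(cand, recs)
    # sweep-line oracle on base coverage
    covered <- rep(FALSE, 40)
    for (i in 1:10) covered[(cand$start[i] + 1):cand$end[i]] <- TRUE
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    expect_equal(merged$start, starts[runs$values] - 1L)
    expect_equal(merged$end, ends[runs$values])
    # pairwise disjoint
    if (nrow(merged) > 1) {
      expect_true(all(merged$start[-1] > merged$end[-nrow(merged)]))
    }
  }
})

test_that("PPMs summarize width groups with pseudocounts and support", {
  inst <- data.frame(sequence_id = "s", start = 0L, end = 3L, width = 3L,
                     subsequence = c("AAA", "AAC"))
  mot <- build_motifs(inst, min_support = 2L, pseudocount = 0)
  expect_length(mot, 1L)
  expect_equal(unname(mot[[1]]$ppm["A", 3]), 0.5)
  expect_equal(unname(mot[[1]]$ppm["C", 3]), 0.5)
  expect_equal(unname(colSums(mot[[1]]$ppm)), rep(1, 3), tolerance = 1e-9)

  single <- data.frame(sequence_id = "s", start = 0L, end = 4L, width = 4L,
                       subsequence = "ACGT")
  expect_message(none <- build_motifs(single, min_support = 2L), "dropped")
  expect_length(none, 0L)
})

test_that("empirical PPMs recover the generating PPM within sampling error", {
  ppm <- default_planted_ppm("TGACTCAG", 0.9)
  set.seed(77)
  draws <- replicate(20, paste(
    vapply(1:8, function(j) {
      sample(c("A", "C", "G", "T"), 1, prob = ppm[, j])
    }, ""), collapse = ""))
  inst <- data.frame(sequence_id = "s", start = 0L, end = 8L, width = 8L,
                     subsequence = draws)
  mot <- build_motifs(inst, min_support = 5L, pseudocount = 0.01)
  expect_length(mot, 1L)
  expect_lte(mean(abs(mot[[1]]$ppm - ppm)), 0.15)
  expect_gte(ppm_correlation(mot[[1]]$ppm, ppm), 0.8)
})

test_that("MEME export round-trips and rejects empty motif lists", {
  inst <- data.frame(sequence_id = "s", start = 0L, end = 3L, width = 3L,
                     subsequence = c("AAA", "AAC", "AGC"))
  mot <- build_motifs(inst, min_support = 2L)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(mot, f, background_freqs = c(0.3, 0.2, 0.2, 0.3))
  txt <- readLines(f)
  expect_true(any(grepl("MEME version 4", txt)))
  expect_true(any(grepl("w= 3", txt)))
  expect_equal(sum(grepl("^ [0-9]", txt)), 3L)
  back <- read_meme(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$ppm, round(mot[[1]]$ppm, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back[[1]]$support, 3L)
  expect_error(write_meme(list(), f), "no motifs")
})

test_that("instance BED output uses 0-based half-open coordinates", {
  inst <- data.frame(sequence_id = c("p1", "p2"), start = c(3L, 0L),
                     end = c(11L, 5L), width = c(8L, 5L),
                     subsequence = c("ACGTACGT", "TTTTT"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_tfbs_bed(inst, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, c(3L, 0L))
  expect_equal(bed$V3, c(11L, 5L))
})
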