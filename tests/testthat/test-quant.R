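make_reads <- function(bases, qual = NULL) {
  if (is.null(qual)) qual <- vapply(nchar(bases), function(L) {
    phred_encode(rep(40L, L))
  }, character(1))
  fastq_reads(sprintf("r%03d", seq_along(bases)), bases, qual)
}

test_that("high-quality reads pass trimming unchanged", {
  r <- make_reads(strrep("A", 100))
  out <- trim_reads(r, trim_params())
  expect_equal(out$reads$bases, r$bases)
  expect_equal(out$n_discarded, 0L)
})

test_that("reads shorter than min_len are discarded", {
  r <- make_reads(strrep("A", 49))
  out <- trim_reads(r, trim_params())
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$discarded_ids, "r001")
})

test_that("a crafted low-quality tail is trimmed at the expected base", {
  qual <- phred_encode(c(rep(30L, 55), rep(2L, 5)))
  r <- make_reads(strrep("C", 60), qual)
  out <- trim_reads(r, trim_params())
  expect_equal(nchar(out$reads$bases), 55L)
  rng <- oracle_trim(phred_decode(qual)[[1]])
  expect_equal(nchar(out$reads$bases), rng[2] - rng[1] + 1L)
})

test_that("trimming matches the step-by-step oracle on random reads", {
  withr::local_seed(14)
  for (i in 1:50) {
    L <- sample(40:120, 1)
    q <- sample(0:40, L, replace = TRUE)
    bases <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
    r <- make_reads(bases, phred_encode(q))
    out <- trim_reads(r, trim_params(min_len = 20))
    rng <- oracle_trim(q, minlen = 20)
    if (is.null(rng)) {
      expect_equal(nrow(out$reads), 0L)
    } else {
      expect_equal(out$reads$bases, substr(bases, rng[1], rng[2]))
      # trimmed read is a contiguous substring: no bases reordered
      expect_true(grepl(out$reads$bases, bases, fixed = TRUE))
    }
  }
})

test_that("demultiplexing requires the barcode pair to match jointly", {
  bc <- data.frame(sample_id = c("S1", "S2"),
                   left = c("AAAA", "CCCC"), right = c("TTTT", "GGGG"))
  insert <- strrep("ACGT", 10)
  reads <- make_reads(c(paste0("AAAA", insert, "GGGG"),   # S1 left, S2 right
                        paste0("AAAA", insert, "TTTT"),
                        paste0("CCCC", insert, "GGGG")))
  dm <- demultiplex(reads, bc)
  expect_equal(nrow(dm$unassigned), 1L)
  expect_equal(nrow(dm$samples$S1), 1L)
  expect_equal(nrow(dm$samples$S2), 1L)
  expect_equal(dm$samples$S1$bases, insert)  # barcodes stripped
})

test_that("duplicate barcode pairs are a configuration error", {
  bc <- data.frame(sample_id = c("a", "b"),
                   left = c("AA", "AA"), right = c("TT", "TT"))
  expect_error(demultiplex(make_reads("AATT"), bc), "duplicate")
})

test_that("demultiplexing recovers simulated per-sample counts", {
  withr::local_seed(13)
  n_samples <- 32
  bc <- data.frame(sample_id = sprintf("S%02d", 1:n_samples),
                   left = random_dna(n_samples, 6),
                   right = random_dna(n_samples, 6))
  stopifnot(!anyDuplicated(paste(bc$left, bc$right)))
  insert <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  assign <- sample(n_samples, 10000, replace = TRUE)
  reads <- make_reads(paste0(bc$left[assign], insert, bc$right[assign]))
  dm <- demultiplex(reads, bc)
  expect_equal(unname(vapply(dm$samples, nrow, integer(1))),
               as.integer(table(factor(assign, levels = 1:n_samples))))
  expect_equal(nrow(dm$unassigned), 0L)
})

test_that("read classification follows the C-to-T rule", {
  withr::local_seed(15)
  amp <- make_amplicon(random_spacer(c_at = c(2, 5, 11)))
  ref <- amp$reference
  site <- amp$site
  pos5 <- site$amp_positions[5]
  sub_at <- function(s, i, ch) {
    substr(s, i, i) <- ch
    s
  }
  reads <- c(ref,                      # identical -> unedited
             sub_at(ref, pos5, "T"),   # targeted C->T -> edited
             sub_at(ref, pos5, "G"),   # non-C->T substitution -> unedited
             substr(ref, pos5, nchar(ref)))  # starts inside site -> not covering
  cl <- classify_reads(reads, ref, site)
  expect_equal(as.character(cl$status),
               c("unedited", "edited", "unedited", "not_covering"))
  expect_equal(cl$n_converted, c(0L, 1L, 0L, 0L))
})

test_that("classification matches a position-by-position oracle", {
  withr::local_seed(17)
  amp <- make_amplicon(random_spacer(c_at = c(1, 4, 7, 13)))
  site <- amp$site
  sim <- simulate_sample_reads(amp$reference,
                               site_edits(site, 0.3), depth = 500,
                               subst_error = 0.002, indel_prob = 0)
  cl <- classify_reads(sim$reads, amp$reference, site)
  # indel-free equal-length reads: direct substring comparison is an oracle
  tpos <- site$amp_positions[site$c_positions]
  oracle_status <- vapply(sim$reads$bases, function(b) {
    if (any(substring(b, tpos, tpos) == "T")) "edited" else "unedited"
  }, character(1), USE.NAMES = FALSE)
  expect_equal(as.character(cl$status), oracle_status)
})

test_that("minus-strand sites read G-to-A conversions", {
  withr::local_seed(16)
  amp <- make_amplicon(random_spacer(c_at = c(3, 7)), strand = "-")
  site <- amp$site
  expect_equal(site$c_positions, c(3L, 7L))
  sim <- simulate_sample_reads(amp$reference,
                               site_edits(site, c("7" = 1.0)),
                               depth = 30, subst_error = 0)
  st <- quantify_sample(sim$reads, amp$reference, site)
  expect_equal(st$n_edited, 30L)
  expect_equal(st$per_position_edited[7], 30L)
  expect_equal(st$per_position_edited[3], 0L)
})

test_that("classification conserves reads across the three classes", {
  withr::local_seed(18)
  amp <- make_amplicon(random_spacer(c_at = c(5, 9)))
  sim <- simulate_sample_reads(amp$reference, site_edits(amp$site, 0.2),
                               depth = 400, indel_prob = 0.05,
                               subst_error = 0.002)
  st <- quantify_sample(sim$reads, amp$reference, amp$site)
  expect_equal(st$n_edited + st$n_unedited + st$n_not_covering, st$n_clean)
  expect_lte(st$n_indel, st$n_clean)
})

test_that("compute_efficiency is the edited fraction of clean reads", {
  st <- structure(list(n_clean = 1000L, n_edited = 253L),
                  class = "sample_edit_stats")
  expect_equal(compute_efficiency(st), 25.3)
  st$n_edited <- 0L
  expect_equal(compute_efficiency(st), 0)
  st$n_clean <- 0L
  expect_true(is.na(compute_efficiency(st)))
})

test_that("efficiency recovers a simulated 20% editing rate", {
  withr::local_seed(19)
  amp <- make_amplicon(random_spacer(c_at = 5))
  sim <- simulate_sample_reads(amp$reference,
                               site_edits(amp$site, 0.20), depth = 2000,
                               subst_error = 0)
  st <- quantify_sample(sim$reads, amp$reference, amp$site)
  se <- 100 * sqrt(0.2 * 0.8 / 2000)
  expect_lt(abs(compute_efficiency(st) - 20), 3 * se)
})

test_that("per-position matrix has NA rows for C-free spacers and [0,1] entries", {
  withr::local_seed(23)
  amp1 <- make_amplicon(random_spacer(c_at = 5), gRNA_id = "gC5")
  amp0 <- make_amplicon(random_spacer(c_at = integer(0)), gRNA_id = "gNoC")
  sim1 <- simulate_sample_reads(amp1$reference,
                                site_edits(amp1$site, 0.25), depth = 2000,
                                subst_error = 0.001)
  sim0 <- simulate_sample_reads(amp0$reference,
                                site_edits(amp0$site, 0.25), depth = 200,
                                subst_error = 0.001)
  st1 <- quantify_sample(sim1$reads, amp1$reference, amp1$site)
  st0 <- quantify_sample(sim0$reads, amp0$reference, amp0$site)
  mat <- per_position_matrix(list(st1, st0))
  expect_true(all(is.na(mat["gNoC", ])))
  expect_true(all(mat[!is.na(mat)] >= 0 & mat[!is.na(mat)] <= 1))
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(mat["gC5", 5] - 0.25), 3 * se)
  expect_true(all(is.na(mat["gC5", setdiff(1:20, 5)])))
})

test_that("window profile reproduces the designed/edited ratio", {
  mat <- matrix(NA_real_, 16, 20, dimnames = list(NULL, paste0("C", 1:20)))
  mat[, 1] <- c(0.05, 0.02, rep(0.001, 14))  # 16 designed, 2 above threshold
  wp <- window_profile(mat, detection_threshold = 0.005)
  expect_equal(wp$designed[1], 16L)
  expect_equal(wp$edited[1], 2L)
  expect_equal(wp$probability[1], 0.125)
  expect_true(all(is.na(wp$probability[2:20])))
})

test_that("a control sample raises the detection threshold", {
  mat <- matrix(NA_real_, 4, 20)
  mat[, 3] <- c(0.02, 0.02, 0.004, 0.001)
  ctrl <- rep(0, 20)
  ctrl[3] <- 0.01  # 3x control = 0.03 beats all entries
  expect_equal(window_profile(mat)$edited[3], 2L)
  expect_equal(window_profile(mat, control_rates = ctrl)$edited[3], 0L)
})

test_that("a planted 4-8 window is recovered with zero noise", {
  withr::local_seed(29)
  stats <- list()
  for (i in 1:12) {
    c_at <- sort(sample(1:20, 4))
    amp <- make_amplicon(random_spacer(c_at = c_at),
                         gRNA_id = sprintf("g%02d", i))
    p <- ifelse(c_at >= 4 & c_at <= 8, 0.3, 0)
    names(p) <- c_at
    sim <- simulate_sample_reads(amp$reference, site_edits(amp$site, p),
                                 depth = 300, subst_error = 0)
    stats[[i]] <- quantify_sample(sim$reads, amp$reference, amp$site)
  }
  wp <- window_profile(per_position_matrix(stats))
  positive <- which(!is.na(wp$probability) & wp$probability > 0)
  expect_true(all(positive >= 4 & positive <= 8))
  inside <- which(!is.na(wp$probability[4:8])) + 3
  expect_true(all(wp$probability[inside] == 1))
})

test_that("multiplex counting tallies distinct converted target positions", {
  withr::local_seed(20)
  tiled <- make_tiled_amplicon(vapply(1:4, function(i) {
    random_spacer(c_at = c(2, 6, 10, 14))
  }, character(1)))
  ref <- tiled$reference
  tpos <- sort(unlist(lapply(tiled$sites, function(s) {
    s$amp_positions[s$c_positions]
  })))
  expect_equal(length(tpos), 16L)
  edit_first <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- "T"
    s
  }
  reads <- c(ref, edit_first(ref, tpos[1:14]), edit_first(ref, tpos[5]))
  h <- multiplex_histogram(reads, ref, tiled$sites)
  expect_equal(h$max_k, 14L)
  expect_equal(as.integer(h$counts[c("0", "1", "14")]), c(1L, 1L, 1L))
  expect_equal(sum(h$counts), h$n_reads)
  # duplicated sites share all positions: union semantics count them once
  h2 <- multiplex_histogram(reads, ref, c(tiled$sites, tiled$sites[1]))
  expect_equal(h2$n_targeted_positions, 16L)
  expect_equal(h2$counts, h$counts)
})

test_that("multiplex histogram matches the binomial law of independent edits", {
  withr::local_seed(31)
  tiled <- make_tiled_amplicon(vapply(1:3, function(i) {
    random_spacer(c_at = c(3, 8, 13, 18))
  }, character(1)))
  m <- sum(vapply(tiled$sites, function(s) length(s$c_positions), integer(1)))
  p <- 0.1
  edits <- do.call(rbind, lapply(tiled$sites, site_edits, prob = p))
  sim <- simulate_sample_reads(tiled$reference, edits, depth = 3000,
                               subst_error = 0, indel_prob = 0)
  h <- multiplex_histogram(sim$reads, tiled$reference, tiled$sites)
  obs <- rep(0L, m + 1)
  obs[as.integer(names(h$counts)) + 1] <- as.integer(h$counts)
  expected <- stats::dbinom(0:m, m, p)
  # pool the sparse upper tail so expected counts stay reasonable
  cut <- max(which(expected * sum(obs) >= 5))
  obs_p <- c(obs[seq_len(cut - 1)], sum(obs[cut:(m + 1)]))
  exp_p <- c(expected[seq_len(cut - 1)], sum(expected[cut:(m + 1)]))
  gof <- stats::chisq.test(obs_p, p = exp_p)
  expect_gt(gof$p.value, 0.01)
})

test_that("indel calling flags gapped alignments only", {
  withr::local_seed(21)
  ref <- make_amplicon(random_spacer(c_at = 5))$reference
  del3 <- paste0(substr(ref, 1, 60), substr(ref, 64, nchar(ref)))
  sub1 <- ref
  substr(sub1, 70, 70) <- chartr("ACGT", "TGCA", substr(ref, 70, 70))
  fr <- indel_frequency(c(ref, del3, sub1), ref)
  expect_equal(fr$flags, c(FALSE, TRUE, FALSE))
  expect_equal(fr$percent, 33.3)
})

test_that("indel frequency recovers a simulated 5% rate and is exact on clean reads", {
  withr::local_seed(37)
  amp <- make_amplicon(random_spacer(c_at = 5))
  sim <- simulate_sample_reads(amp$reference, site_edits(amp$site, 0),
                               depth = 1000, indel_prob = 0.05,
                               subst_error = 0.001)
  fr <- indel_frequency(sim$reads, amp$reference)
  se <- 100 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(fr$percent - 5), 3 * se)
  # substitution-only reads, zero error: exactly 0
  sim0 <- simulate_sample_reads(amp$reference, site_edits(amp$site, 0.4),
                                depth = 500, indel_prob = 0,
                                subst_error = 0)
  expect_equal(indel_frequency(sim0$reads, amp$reference)$percent, 0)
})

test_that("clone efficiency reproduces printed clone percentages", {
  expect_equal(clone_efficiency(7, 12), 58.3)
  expect_equal(clone_efficiency(3, 11), 27.2)
  expect_equal(clone_efficiency(2, 5), 40.0)
  expect_equal(clone_efficiency(21, 41), 51.2)
  expect_equal(clone_efficiency(0, 10), 0.0)
  expect_true(is.na(clone_efficiency(0, 0)))
  expect_error(clone_efficiency(5, 3))
})

test_that("efficiency estimation is unbiased over replicate simulations", {
  withr::local_seed(1)
  amp <- make_amplicon(random_spacer(c_at = 5))
  est <- vapply(100:299, function(seed) {
    sim <- simulate_sample_reads(amp$reference, site_edits(amp$site, 0.2),
                                 depth = 400, subst_error = 0, seed = seed)
    compute_efficiency(quantify_sample(sim$reads, amp$reference, amp$site))
  }, numeric(1))
  expect_lt(abs(mean(est) - 20), 0.5)
})
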