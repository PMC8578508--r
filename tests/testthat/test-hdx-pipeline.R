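test_that("uptake tables round-trip through CSV and validate structure", {
  st <- small_study(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_uptake_table(st$records, path)
  back <- read_uptake_table(path)
  for (col in c("Start", "End", "Sequence", "State", "Exposure",
                "Replicate"))
    expect_equal(back[[col]], st$records[[col]])
  expect_equal(back$Center, st$records$Center, tolerance = 1e-9)
  expect_equal(back$Uptake, st$records$Uptake, tolerance = 1e-9)
  # missing column
  df <- st$records; df$Center <- NULL
  expect_error(validate_uptake_table(df), "missing column")
  # malformed bounds are rejected with the row number
  df <- as.data.frame(st$records)
  df$Start[5] <- df$End[5] + 1L
  expect_error(validate_uptake_table(df), "row 5")
  # duplicate (peptide, state, exposure, replicate)
  df <- as.data.frame(st$records)
  expect_error(validate_uptake_table(rbind(df, df[1, ])), "duplicate")
})

test_that("records without a time-0 reference are flagged, not invented", {
  st <- small_study(seed = 2)
  df <- as.data.frame(st$records)
  pep <- paste(df$Start, df$End, df$State)
  drop_key <- pep[df$Exposure == 0][1]
  df <- df[!(pep == drop_key & df$Exposure == 0), ]
  out <- validate_uptake_table(df)
  pep2 <- paste(out$Start, out$End, out$State)
  expect_true(all(is.na(out$Uptake[pep2 == drop_key])))
  expect_true(all(!out$has_t0[pep2 == drop_key]))
  expect_true(all(out$has_t0[pep2 != drop_key]))
})

test_that("uptake is the centroid difference", {
  expect_equal(compute_uptake(1250.60, 1248.35), 2.25)
  expect_equal(compute_uptake(500, 500), 0)
  expect_error(compute_uptake(NA_real_, 1), "finite")
  # on synthetic data the measured uptake equals the model value +/- noise
  st <- small_study(seed = 4)
  truth <- expected_uptake(st$model, st$map, labeling_protocol(seed = 4),
                           "unphos")
  rec <- st$records[st$records$State == "unphos" &
                      st$records$Exposure == 180, ]
  key <- match(paste(rec$Start, rec$End), paste(st$map$start, st$map$end))
  # noise SD 0.05 on each of t and t0 centroids; 6 sigma bound
  expect_true(all(abs(rec$Uptake - truth[key, 4]) < 6 * 0.05 * sqrt(2)))
})

test_that("the significance rule gates on both thresholds", {
  mk <- function(delta, sd) {
    # two states, 3 replicates, one timepoint, sd_diff = sqrt(2) * sd_rep
    sd_rep <- sd / sqrt(2)
    reps <- c(-1, 0, 1) * sd_rep  # mean 0, sd = sd_rep exactly
    base <- 1000
    df <- rbind(
      data.frame(Protein = "x", Start = 1, End = 10, Sequence = "ACDEFGHIKL",
                 State = "A", Exposure = c(0, 0, 0, 1, 1, 1),
                 Replicate = rep(1:3, 2),
                 Center = c(base, base, base, base + delta + reps)),
      data.frame(Protein = "x", Start = 1, End = 10, Sequence = "ACDEFGHIKL",
                 State = "B", Exposure = c(0, 0, 0, 1, 1, 1),
                 Replicate = rep(1:3, 2),
                 Center = c(base, base, base, base + reps)))
    hdx_differential(df, "A", "B")$by_timepoint
  }
  # 0.6 Da with sd_diff 0.1: passes both gates
  expect_true(mk(0.6, 0.1)$significant)
  expect_equal(mk(0.6, 0.1)$delta, 0.6, tolerance = 1e-9)
  expect_equal(mk(0.6, 0.1)$sd_diff, 0.1, tolerance = 1e-9)
  # 0.6 Da with sd_diff 0.30: fails 2.3 x SD (0.69)
  expect_false(mk(0.6, 0.30)$significant)
  # 0.4 Da with tiny SD: fails the absolute 0.5 Da gate
  expect_false(mk(0.4, 0.01)$significant)
})

test_that("raising either threshold never adds significant calls", {
  st <- small_study(seed = 6)
  base <- hdx_differential(st$records, "unphos", "phos",
                           significance_config(0.5, 2.3))
  n_base <- sum(base$by_timepoint$significant)
  for (cfg in list(significance_config(0.8, 2.3),
                   significance_config(0.5, 4),
                   significance_config(1.2, 6))) {
    n <- sum(hdx_differential(st$records, "unphos", "phos",
                              cfg)$by_timepoint$significant)
    expect_lte(n, n_base)
  }
  # absent state errors
  expect_error(hdx_differential(st$records, "unphos", "nope"), "absent")
})

test_that("EX1-flagged peptides project as zero difference", {
  st <- small_study(seed = 7)
  d0 <- hdx_differential(st$records, "unphos", "phos")
  sig <- d0$by_peptide[d0$by_peptide$any_significant, ]
  skip_if(nrow(sig) == 0)
  flag <- sig[1, c("Start", "End")]
  d1 <- hdx_differential(st$records, "unphos", "phos",
                         ex1_peptides = flag)
  row <- d1$by_peptide$Start == flag$Start & d1$by_peptide$End == flag$End
  expect_true(d1$by_peptide$ex1_flag[row])
  expect_equal(d1$by_peptide$summary_delta[row], 0)
  expect_false(d1$by_peptide$any_significant[row])
})

test_that("residue projection reproduces the averaging formula", {
  cs <- construct(strrep("A", 30), name = "flat")
  # one covering peptide: delta 0.9 over 8 exchanging residues
  map1 <- data.frame(start = 1L, end = 9L)
  diff1 <- data.frame(Start = 1L, End = 9L, summary_delta = 0.9)
  p1 <- residue_projection(diff1, map1, cs)
  expect_equal(p1$value[2:9], rep(0.9 / 8, 8), tolerance = 1e-12)
  expect_false(p1$covered[1])   # first residue never exchanges
  expect_false(any(p1$covered[10:30]))
  # two overlapping peptides: mean of pep_i / amide_i
  map2 <- data.frame(start = c(1L, 4L), end = c(9L, 9L))
  diff2 <- data.frame(Start = c(1L, 4L), End = c(9L, 9L),
                      summary_delta = c(0.9, 0.5))
  p2 <- residue_projection(diff2, map2, cs)
  expect_equal(p2$value[5:9], rep((0.9 / 8 + 0.5 / 5) / 2, 5),
               tolerance = 1e-12)
  expect_equal(p2$value[2:3], rep(0.9 / 8, 2), tolerance = 1e-12)
  expect_equal(p2$n_peptides[5:9], rep(2L, 5))
})

test_that("projection equals a brute-force oracle on random maps", {
  for (seed in 1:25) {
    st <- small_study(seed = seed, n_residues = 80L, protected_start = 31L,
                      protected_end = 50L)
    d <- hdx_differential(st$records, "unphos", "phos")
    prof <- residue_projection(d, st$map)
    # independent loop over (residue, peptide) pairs
    chars <- strsplit(st$construct$sequence, "")[[1]]
    for (j in sample(seq_len(80), 12)) {
      vals <- c()
      for (i in seq_len(nrow(st$map))) {
        ex <- exchanging_oracle(chars, st$map$start[i], st$map$end[i])
        if (!(j %in% ex)) next
        k <- which(d$by_peptide$Start == st$map$start[i] &
                     d$by_peptide$End == st$map$end[i])
        vals <- c(vals, d$by_peptide$summary_delta[k] / length(ex))
      }
      if (length(vals)) {
        expect_equal(prof$value[j], mean(vals), tolerance = 1e-12)
        expect_equal(prof$n_peptides[j], length(vals))
      } else {
        expect_false(prof$covered[j])
      }
    }
  }
})

test_that("projection is linear in the deltas and uniform maps are flat", {
  cs <- construct(strrep("A", 40))
  map <- data.frame(start = c(1, 6, 11, 16, 21), end = c(10, 15, 20, 25, 30))
  d1 <- data.frame(Start = map$start, End = map$end,
                   summary_delta = c(0.2, 0.5, -0.3, 0.8, 0.1))
  d3 <- d1; d3$summary_delta <- 3 * d1$summary_delta
  p1 <- residue_projection(d1, map, cs)
  p3 <- residue_projection(d3, map, cs)
  expect_equal(p3$value[p3$covered], 3 * p1$value[p1$covered],
               tolerance = 1e-12)
  # equal deltas c with equal amide counts n give c/n wherever covered
  dflat <- d1; dflat$summary_delta <- 0.45
  # peptides 2..5 all have 9 exchanging residues
  pflat <- residue_projection(dflat[2:5, ], map[2:5, ], cs)
  expect_equal(unique(round(pflat$value[pflat$covered], 12)),
               round(0.45 / 9, 12))
})

test_that("region calling finds uniform-sign runs and honours gaps", {
  prof <- data.frame(residue = 1:60, value = 0, n_peptides = 1L,
                     covered = TRUE)
  class(prof) <- c("residue_profile", "data.frame")
  # all-zero profile: nothing called
  expect_equal(nrow(call_protected_regions(prof, min_abs = 0.1)), 0L)
  expect_equal(nrow(call_protected_regions(prof)), 0L)  # half-max rule
  # one 22-residue block at +0.2
  prof$value[20:41] <- 0.2
  got <- call_protected_regions(prof, min_abs = 0.1, min_run = 5)
  expect_equal(got[, c("start", "end", "sign")],
               data.frame(start = 20L, end = 41L, sign = 1))
  # a coverage gap splits the run
  prof$covered[30] <- FALSE; prof$value[30] <- NA
  got2 <- call_protected_regions(prof, min_abs = 0.1, min_run = 5)
  expect_equal(got2$start, c(20L, 31L))
  expect_equal(got2$end, c(29L, 41L))
  # opposite signs split the run
  prof$covered[30] <- TRUE; prof$value[30] <- -0.2
  got3 <- call_protected_regions(prof, min_abs = 0.1, min_run = 5)
  expect_equal(got3$start, c(20L, 31L))
  # min_run filters short runs
  expect_equal(nrow(call_protected_regions(prof, min_abs = 0.1,
                                           min_run = 15)), 0L)
})

test_that("coverage summary equals a brute-force residue count", {
  st <- small_study(seed = 9, n_residues = 100L)
  regions <- data.frame(label = c("r1", "r2", "r3"),
                        start = c(1, 41, 81), end = c(40, 80, 100))
  got <- coverage_summary(st$map, st$construct, regions)
  chars <- strsplit(st$construct$sequence, "")[[1]]
  covered <- logical(100)
  for (i in seq_len(nrow(st$map)))
    covered[exchanging_oracle(chars, st$map$start[i], st$map$end[i])] <- TRUE
  for (k in 1:3) {
    idx <- regions$start[k]:regions$end[k]
    expect_equal(got$fraction[k], mean(covered[idx]))
  }
  # full tiling reaches 1 on interior regions; empty map gives 0
  empty <- data.frame(start = integer(), end = integer())
  got0 <- coverage_summary(empty, st$construct, regions)
  expect_equal(got0$fraction, c(0, 0, 0))
})
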