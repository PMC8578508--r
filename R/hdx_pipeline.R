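#' Read and validate a peptide uptake table
#'
#' Expects a DynamX-cluster-style CSV with columns `Protein`, `Start`,
#' `End`, `Sequence`, `State`, `Exposure`, `Replicate`, `Center` (an
#' optional `Uptake` column is ignored on read and recomputed). Validation
#' rejects missing columns, rows with `Start > End`, and duplicate
#' (peptide, state, exposure, replicate) combinations. Deuterium uptake is
#' computed per record as the centroid minus the mean time-0 centroid of
#' the same peptide and state; records without a time-0 reference get
#' `Uptake = NA` and `has_t0 = FALSE`.
#'
#' @param path CSV file.
#' @return data.frame of class `uptake_table` with the columns above plus
#'   `Uptake` and `has_t0`.
#' @export
read_uptake_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_uptake_table(df)
}

#' @rdname read_uptake_table
#' @param records a data.frame of uptake records (e.g. from
#'   [simulate_uptake()]).
#' @export
validate_uptake_table <- function(records) {
  required <- c("Protein", "Start", "End", "Sequence", "State", "Exposure",
                "Replicate", "Center")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("uptake table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- which(records$Start > records$End)
  if (length(bad))
    stop("row ", bad[1L], ": Start (", records$Start[bad[1L]],
         ") greater than End (", records$End[bad[1L]], ")", call. = FALSE)
  if (any(records$Exposure < 0))
    stop("negative exposure time", call. = FALSE)
  key <- paste(records$Start, records$End, records$Sequence, records$State,
               records$Exposure, records$Replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (peptide, state, exposure, replicate) at row ",
         which(duplicated(key))[1L], call. = FALSE)
  records <- compute_uptake_column(records)
  class(records) <- c("uptake_table", "data.frame")
  records
}

# uptake = centroid(t) - mean centroid(t0) per peptide/state
compute_uptake_column <- function(records) {
  pep_state <- paste(records$Start, records$End, records$Sequence,
                     records$State, sep = "\r")
  t0 <- records$Exposure == 0
  t0_mean <- tapply(records$Center[t0], pep_state[t0], mean)
  ref <- t0_mean[pep_state]
  records$Uptake <- ifelse(is.na(ref), NA_real_, records$Center - ref)
  records$has_t0 <- !is.na(ref)
  records
}

#' @rdname read_uptake_table
#' @export
write_uptake_table <- function(records, path) {
  keep <- intersect(c("Protein", "Start", "End", "Sequence", "State",
                      "Exposure", "Replicate", "Center", "Uptake"),
                    names(records))
  utils::write.csv(as.data.frame(records)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Deuterium uptake from centroids
#'
#' @param centroid_t centroid mass at exposure t (Da).
#' @param centroid_0 centroid mass of the undeuterated (time-0) control.
#' @return Uptake in Da.
#' @export
compute_uptake <- function(centroid_t, centroid_0) {
  stopifnot(all(is.finite(centroid_t)), all(is.finite(centroid_0)))
  centroid_t - centroid_0
}

#' Significance configuration for differential HDX
#'
#' A peptide/timepoint difference is significant when `|delta|` exceeds the
#' absolute threshold (default 0.5 Da) AND `sd_multiplier` (default 2.3)
#' times the standard deviation of the difference. `sd_mode` selects how
#' that SD is computed: `"per_peptide"` propagates replicate SDs per peptide
#' and timepoint, `sd_diff = sqrt(sd_A^2 + sd_B^2)`; `"pooled"` uses the
#' root-mean-square of all per-peptide `sd_diff` values as one global SD.
#'
#' @param abs_threshold absolute threshold, Da (> 0).
#' @param sd_multiplier SD multiplier (> 0).
#' @param sd_mode `"per_peptide"` (default) or `"pooled"`.
#' @return Object of class `significance_config`.
#' @export
significance_config <- function(abs_threshold = 0.5, sd_multiplier = 2.3,
                                sd_mode = c("per_peptide", "pooled")) {
  stopifnot(abs_threshold > 0, sd_multiplier > 0)
  sd_mode <- match.arg(sd_mode)
  structure(list(abs_threshold = abs_threshold, sd_multiplier = sd_multiplier,
                 sd_mode = sd_mode),
            class = "significance_config")
}

#' Differential HDX between two states
#'
#' For every peptide and exposure time, computes the mean uptake difference
#' `delta = mean_A - mean_B` with replicate-propagated
#' `sd_diff = sqrt(sd_A^2 + sd_B^2)` and applies the significance rule of
#' the supplied [significance_config()]. The per-peptide summary is the
#' mean over exposure times of the per-timepoint deltas, with
#' non-significant timepoints contributing 0; peptides flagged as EX1 are
#' forced to a summary of 0 (EX1 regions are treated as showing no
#' difference).
#'
#' @param records an uptake table (see [read_uptake_table()]).
#' @param state_a,state_b state labels; positive `delta` means higher
#'   uptake in `state_a`.
#' @param config a [significance_config()].
#' @param ex1_peptides optional data.frame with `Start`, `End` (and
#'   optionally `Sequence`) identifying EX1-flagged peptides.
#' @return Object of class `hdx_differential`: list with `by_timepoint`
#'   (peptide x exposure rows: `delta`, `sd_diff`, `significant`,
#'   `ex1_flag`) and `by_peptide` (per-peptide `summary_delta`,
#'   `any_significant`, `ex1_flag`).
#' @export
hdx_differential <- function(records, state_a, state_b,
                             config = significance_config(),
                             ex1_peptides = NULL) {
  stopifnot(inherits(config, "significance_config"))
  if (!inherits(records, "uptake_table")) records <- validate_uptake_table(records)
  for (s in c(state_a, state_b))
    if (!s %in% records$State)
      stop("state '", s, "' absent from uptake table", call. = FALSE)
  rec <- records[records$State %in% c(state_a, state_b) &
                   records$Exposure > 0 & records$has_t0, , drop = FALSE]
  pep_key <- paste(rec$Start, rec$End, rec$Sequence, sep = "\r")
  # tolerance-based timepoint matching (1e-9 min)
  tp <- sort(unique(rec$Exposure))
  if (length(tp) > 1L && any(diff(tp) < 1e-9))
    tp <- tp[c(TRUE, diff(tp) >= 1e-9)]
  rec$tp <- tp[vapply(rec$Exposure,
                      function(e) which.min(abs(tp - e)), integer(1))]
  agg <- function(state) {
    r <- rec[rec$State == state, ]
    k <- paste(r$Start, r$End, r$Sequence, r$tp, sep = "\r")
    n <- tapply(r$Uptake, k, length)
    list(mean = tapply(r$Uptake, k, mean),
         sd = tapply(r$Uptake, k, stats::sd), n = n)
  }
  a <- agg(state_a); b <- agg(state_b)
  keys <- intersect(names(a$mean), names(b$mean))
  if (!length(keys))
    stop("no peptide/timepoint present in both states", call. = FALSE)
  if (any(a$n[keys] < 3) || any(b$n[keys] < 3))
    warning("fewer than 3 replicates for some peptide/timepoints")
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  by_tp <- data.frame(Start = as.integer(parts[, 1]),
                      End = as.integer(parts[, 2]),
                      Sequence = parts[, 3],
                      Exposure = as.numeric(parts[, 4]),
                      delta = as.numeric(a$mean[keys] - b$mean[keys]),
                      sd_diff = sqrt(ifelse(is.na(a$sd[keys]), 0,
                                            a$sd[keys])^2 +
                                     ifelse(is.na(b$sd[keys]), 0,
                                            b$sd[keys])^2),
                      stringsAsFactors = FALSE)
  sd_eff <- switch(config$sd_mode,
                   per_peptide = by_tp$sd_diff,
                   pooled = rep(sqrt(mean(by_tp$sd_diff^2)), nrow(by_tp)))
  by_tp$significant <- abs(by_tp$delta) > config$abs_threshold &
    abs(by_tp$delta) > config$sd_multiplier * sd_eff
  by_tp$ex1_flag <- FALSE
  if (!is.null(ex1_peptides) && nrow(ex1_peptides) > 0L) {
    ex1_key <- paste(ex1_peptides$Start, ex1_peptides$End, sep = "\r")
    by_tp$ex1_flag <- paste(by_tp$Start, by_tp$End, sep = "\r") %in% ex1_key
  }
  o <- order(by_tp$Start, by_tp$End, by_tp$Exposure)
  by_tp <- by_tp[o, , drop = FALSE]
  rownames(by_tp) <- NULL
  contrib <- ifelse(by_tp$significant & !by_tp$ex1_flag, by_tp$delta, 0)
  pk <- paste(by_tp$Start, by_tp$End, by_tp$Sequence, sep = "\r")
  summary_delta <- tapply(contrib, pk, mean)
  any_sig <- tapply(by_tp$significant & !by_tp$ex1_flag, pk, any)
  ex1 <- tapply(by_tp$ex1_flag, pk, any)
  parts <- do.call(rbind, strsplit(names(summary_delta), "\r", fixed = TRUE))
  by_pep <- data.frame(Start = as.integer(parts[, 1]),
                       End = as.integer(parts[, 2]),
                       Sequence = parts[, 3],
                       summary_delta = ifelse(as.logical(ex1), 0,
                                              as.numeric(summary_delta)),
                       any_significant = as.logical(any_sig) &
                         !as.logical(ex1),
                       ex1_flag = as.logical(ex1),
                       stringsAsFactors = FALSE)
  by_pep <- by_pep[order(by_pep$Start, by_pep$End), , drop = FALSE]
  rownames(by_pep) <- NULL
  structure(list(by_timepoint = by_tp, by_peptide = by_pep,
                 states = c(state_a, state_b), config = config),
            class = "hdx_differential")
}

#' @export
print.hdx_differential <- function(x, ...) {
  cat("<hdx_differential> ", x$states[1], " - ", x$states[2], ": ",
      nrow(x$by_peptide), " peptides, ",
      sum(x$by_timepoint$significant), "/", nrow(x$by_timepoint),
      " significant peptide-timepoints, ",
      sum(x$by_peptide$ex1_flag), " EX1-flagged\n", sep = "")
  invisible(x)
}

#' Project peptide-level differences onto residues
#'
#' Implements the per-residue averaging of overlapping peptides:
#' `res_j = (1/N) * sum_i pep_i / amide_i` over the N peptides in which
#' residue j is an exchanging position (first residue and prolines of a
#' peptide are not exchanging positions). `pep_i` is the per-peptide
#' summary difference (0 for non-significant or EX1-flagged peptides) and
#' `amide_i` its number of exchanging residues. Residues covered by no
#' peptide are reported as gaps (`covered = FALSE`, `value = NA`).
#'
#' @param differential an [hdx_differential()] result, or a data.frame with
#'   `Start`, `End` and a delta column named `summary_delta` (or `delta`).
#' @param map a [generate_peptide_map()] result (defines exchanging
#'   positions via its construct), or any data.frame with `start`, `end`
#'   when `construct` is given.
#' @param construct the construct (defaults to the map's).
#' @return Object of class `residue_profile`: data.frame with `residue`,
#'   `value`, `n_peptides`, `covered`.
#' @export
residue_projection <- function(differential, map,
                               construct = attr(map, "construct")) {
  if (inherits(differential, "hdx_differential"))
    differential <- differential$by_peptide
  dcol <- if ("summary_delta" %in% names(differential)) "summary_delta"
          else "delta"
  stopifnot(inherits(construct, "construct"))
  starts <- if ("start" %in% names(map)) map$start else map$Start
  ends <- if ("end" %in% names(map)) map$end else map$End
  n <- length(construct)
  offset <- construct$offset
  total <- numeric(n)
  count <- integer(n)
  dkey <- paste(differential$Start, differential$End, sep = "\r")
  for (i in seq_along(starts)) {
    j <- match(paste(starts[i], ends[i], sep = "\r"), dkey)
    if (is.na(j)) next
    ex <- .exchanging_residues(construct, starts[i], ends[i])
    amide <- length(ex)
    if (amide < 1L) next
    idx <- ex - offset + 1L
    total[idx] <- total[idx] + differential[[dcol]][j] / amide
    count[idx] <- count[idx] + 1L
  }
  profile <- data.frame(residue = seq_len(n) + offset - 1L,
                        value = ifelse(count > 0L, total / pmax(count, 1L),
                                       NA_real_),
                        n_peptides = count,
                        covered = count > 0L)
  structure(profile, class = c("residue_profile", "data.frame"),
            construct = construct)
}

#' @export
plot.residue_profile <- function(x, ..., main = "Residue-level differential uptake",
                                 ylab = "mean differential uptake (Da/residue)") {
  plot(x$residue, x$value, type = "n", xlab = "residue", ylab = ylab,
       main = main, ...)
  graphics::abline(h = 0, col = "grey70")
  runs <- rle(x$covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values))
    graphics::lines(x$residue[starts[k]:ends[k]],
                    x$value[starts[k]:ends[k]], lwd = 1.5)
  invisible(x)
}

#' Call contiguous protected or exposed regions from a residue profile
#'
#' Maximal runs of at least `min_run` consecutive covered residues whose
#' profile values all satisfy `|value| >= min_abs` with a uniform sign.
#' Coverage gaps break runs. When `min_abs` is `NULL` (the default) a
#' half-maximum rule is used: `min_abs = max(|value|) / 2`, the standard
#' FWHM-style boundary that compensates for the trapezoidal spreading of
#' peptide-level differences across overlapping peptides.
#'
#' @param profile a [residue_projection()] result.
#' @param min_abs minimum per-residue absolute value (Da/residue), or
#'   `NULL` for the half-maximum rule.
#' @param min_run minimum run length in residues (default 5).
#' @return data.frame with `start`, `end`, `sign` (+1 or -1), `mean_value`.
#' @export
call_protected_regions <- function(profile, min_abs = NULL, min_run = 5L) {
  if (is.null(min_abs)) {
    peak <- suppressWarnings(max(abs(profile$value), na.rm = TRUE))
    if (!is.finite(peak) || peak <= 0)
      return(data.frame(start = integer(), end = integer(),
                        sign = numeric(), mean_value = numeric()))
    min_abs <- peak / 2
  }
  stopifnot(min_abs > 0, min_run >= 1L)
  ok <- profile$covered & !is.na(profile$value) &
    abs(profile$value) >= min_abs
  sgn <- sign(profile$value)
  sgn[!ok] <- 0
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0 & runs$lengths >= min_run
  out <- data.frame(start = profile$residue[starts[keep]],
                    end = profile$residue[ends[keep]],
                    sign = runs$values[keep])
  out$mean_value <- vapply(seq_len(nrow(out)), function(i) {
    sel <- profile$residue >= out$start[i] & profile$residue <= out$end[i]
    mean(profile$value[sel])
  }, numeric(1))
  out
}

#' Per-region exchanging-coverage fractions of a peptide map
#'
#' Fraction of each region's residues that are an exchanging position of at
#' least one peptide in the map.
#'
#' @param map a peptide map (data.frame with `start`, `end`).
#' @param construct the construct.
#' @param regions data.frame with `label`, `start`, `end` (defaults to the
#'   construct's regions).
#' @return data.frame with `label`, `n_residues`, `n_covered`, `fraction`.
#' @export
coverage_summary <- function(map, construct = attr(map, "construct"),
                             regions = construct$regions) {
  stopifnot(inherits(construct, "construct"), !is.null(regions))
  n <- length(construct)
  offset <- construct$offset
  covered <- logical(n)
  starts <- if ("start" %in% names(map)) map$start else map$Start
  ends <- if ("end" %in% names(map)) map$end else map$End
  for (i in seq_along(starts)) {
    ex <- .exchanging_residues(construct, starts[i], ends[i])
    covered[ex - offset + 1L] <- TRUE
  }
  out <- data.frame(label = regions$label,
                    n_residues = regions$end - regions$start + 1L)
  out$n_covered <- vapply(seq_len(nrow(regions)), function(i) {
    idx <- (regions$start[i]:regions$end[i]) - offset + 1L
    idx <- idx[idx >= 1L & idx <= n]
    sum(covered[idx])
  }, integer(1))
  out$fraction <- out$n_covered / out$n_residues
  out
}
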