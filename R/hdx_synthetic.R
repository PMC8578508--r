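#' @keywords internal
#' Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Two-state Linderstrom-Lang exchange model
#'
#' Describes amide hydrogen exchange for a construct under one or more
#' conformational states. Each residue j has an intrinsic exchange rate
#' k_int_j (1/min), drawn once from a seeded lognormal distribution, and a
#' per-state protection factor P_j >= 1, so the observed EX2 rate is
#' k_int_j / P_j. A state may additionally carry EX1 segments: intervals
#' that exchange by whole-segment cooperative opening at rate k_op (1/min),
#' producing bimodal isotopic envelopes. Prolines carry no amide hydrogen
#' and never exchange.
#'
#' @param construct a [construct()].
#' @param states named list; each element is a list with
#'   `protection` (scalar or per-residue vector >= 1) and optionally
#'   `ex1` (data.frame with columns `start`, `end`, `k_op`; disjoint
#'   intervals).
#' @param k_base geometric-mean intrinsic rate (1/min, default 10).
#' @param k_sdlog lognormal sdlog of intrinsic rates (default 1).
#' @param seed seed for the intrinsic-rate draw (default 1).
#' @return Object of class `exchange_model`.
#' @examples
#' cs <- construct(paste(rep("ACDEFGHIKL", 4), collapse = ""))
#' m <- exchange_model(cs, states = list(
#'   unphos = list(protection = 50),
#'   phos   = list(protection = 50)))
#' @export
exchange_model <- function(construct, states, k_base = 10, k_sdlog = 1,
                           seed = 1) {
  stopifnot(inherits(construct, "construct"), is.list(states),
            !is.null(names(states)), all(nzchar(names(states))),
            k_base > 0, k_sdlog >= 0)
  n <- length(construct)
  k_int <- with_seed(seed,
                     stats::rlnorm(n, meanlog = log(k_base), sdlog = k_sdlog))
  chars <- .construct_chars(construct)
  offset <- construct$offset
  last <- offset + n - 1L
  states <- lapply(states, function(st) {
    p <- st$protection
    if (is.null(p)) p <- 1
    p <- rep_len(p, n)
    if (any(p < 1)) stop("protection factors must be >= 1", call. = FALSE)
    ex1 <- st$ex1
    if (!is.null(ex1)) {
      ex1 <- as.data.frame(ex1)
      stopifnot(all(c("start", "end", "k_op") %in% names(ex1)))
      if (any(ex1$start > ex1$end) || any(ex1$k_op <= 0))
        stop("invalid EX1 segment", call. = FALSE)
      if (any(ex1$start < offset | ex1$end > last))
        stop("EX1 segment outside construct", call. = FALSE)
      if (nrow(ex1) > 1L) {
        o <- order(ex1$start)
        if (any(ex1$start[o][-1L] <= ex1$end[o][-nrow(ex1)]))
          stop("EX1 segments must be disjoint", call. = FALSE)
      }
    }
    list(protection = p, ex1 = ex1)
  })
  structure(list(construct = construct, k_int = k_int, states = states,
                 proline = chars == "P", seed = seed),
            class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("<exchange_model> on ", x$construct$name, " (", length(x$k_int),
      " residues), states: ", paste(names(x$states), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Deuterium labelling protocol
#'
#' @param times exposure times in minutes, strictly increasing
#'   (default `c(0.05, 0.5, 50, 180)`, i.e. 3 s then 0.5/50/180 min).
#' @param f_D deuterium fraction in the labelling mix (default 0.862:
#'   5 ul protein into 50 ul of 94.8 % D2O buffer, 50/55 x 0.948).
#' @param replicates replicate measurements per timepoint (default 3).
#' @param back_exchange back-exchange fraction b in \[0, 1) (default 0; the
#'   pipeline reports relative deuterium levels without back-exchange
#'   correction).
#' @param noise_sd Gaussian centroid noise SD per replicate, Da
#'   (default 0.05).
#' @param seed RNG seed for replicate noise.
#' @return Object of class `labeling_protocol`.
#' @export
labeling_protocol <- function(times = c(0.05, 0.5, 50, 180), f_D = 0.862,
                              replicates = 3L, back_exchange = 0,
                              noise_sd = 0.05, seed = 1) {
  stopifnot(length(times) >= 1L, all(times > 0), !is.unsorted(times,
            strictly = TRUE), f_D >= 0, f_D <= 1, replicates >= 1L,
            back_exchange >= 0, back_exchange < 1, noise_sd >= 0)
  structure(list(times = times, f_D = f_D, replicates = as.integer(replicates),
                 back_exchange = back_exchange, noise_sd = noise_sd,
                 seed = seed),
            class = "labeling_protocol")
}

# exchanging (amide-bearing) residue numbers of a peptide within a construct:
# all positions except the first, minus prolines
.exchanging_residues <- function(construct, start, end) {
  pos <- (start + 1L):end
  if (start >= end) return(integer())
  chars <- construct_residue(construct, pos)
  pos[chars != "P"]
}

#' Generate an overlapping peptide map
#'
#' Emulates proteolytic (pepsin-style) peptide coverage: random overlapping
#' peptides are accumulated until the mean per-residue coverage (number of
#' peptides in which a residue is an exchanging position) reaches
#' `redundancy`. A first deterministic tiling pass guarantees contiguous
#' coverage where the length range allows. Deterministic for a fixed seed.
#'
#' @param construct a [construct()].
#' @param length_range `c(min, max)` peptide lengths, within \[4, 40\].
#' @param redundancy target mean per-residue coverage (default 3).
#' @param seed RNG seed.
#' @return Object of class `peptide_map`: data.frame with columns `start`,
#'   `end`, `sequence`, `exchangeable_amides`.
#' @export
generate_peptide_map <- function(construct, length_range = c(6, 20),
                                 redundancy = 3, seed = 1) {
  stopifnot(inherits(construct, "construct"), length(length_range) == 2L,
            length_range[1] >= 4, length_range[2] <= 40,
            length_range[1] <= length_range[2], redundancy > 0)
  n <- length(construct)
  offset <- construct$offset
  last <- offset + n - 1L
  lmin <- as.integer(length_range[1]); lmax <- as.integer(length_range[2])
  if (n < lmin)
    stop("construct shorter than minimum peptide length", call. = FALSE)
  # all admissible peptides, to bound achievable coverage
  max_cov <- 0
  for (len in lmin:min(lmax, n))
    max_cov <- max_cov + (n - len + 1) * (len - 1) / n  # proline-free bound
  if (redundancy > max_cov)
    stop("requested redundancy ", redundancy,
         " impossible for this sequence/length range", call. = FALSE)
  peptides <- with_seed(seed, {
    starts <- integer(); ends <- integer()
    add <- function(s, e) {
      if (e > last) e <- last
      if (e - s + 1L >= lmin) { starts <<- c(starts, s); ends <<- c(ends, e) }
    }
    # tiling pass with ~half-length overlap
    step <- max(1L, lmin %/% 2L)
    s <- offset
    while (s <= last - lmin + 1L) {
      add(s, s + lmin + (lmax - lmin) %/% 2L - 1L)
      s <- s + step
    }
    cov <- numeric(n)
    recount <- function() {
      cov <<- numeric(n)
      for (i in seq_along(starts)) {
        ex <- .exchanging_residues(construct, starts[i], ends[i])
        cov[ex - offset + 1L] <<- cov[ex - offset + 1L] + 1
      }
    }
    recount()
    tries <- 0L
    while (mean(cov) < redundancy && tries < 100000L) {
      len <- sample(lmin:lmax, 1L)
      if (len > n) { tries <- tries + 1L; next }
      s <- sample(offset:(last - len + 1L), 1L)
      e <- s + len - 1L
      dup <- any(starts == s & ends == e)
      if (!dup) {
        starts <- c(starts, s); ends <- c(ends, e)
        ex <- .exchanging_residues(construct, s, e)
        cov[ex - offset + 1L] <- cov[ex - offset + 1L] + 1
      }
      tries <- tries + 1L
    }
    if (mean(cov) < redundancy)
      stop("could not reach requested redundancy", call. = FALSE)
    o <- order(starts, ends)
    data.frame(start = starts[o], end = ends[o])
  })
  peptides$sequence <- vapply(seq_len(nrow(peptides)), function(i)
    paste(construct_residue(construct,
                            peptides$start[i]:peptides$end[i]), collapse = ""),
    character(1))
  peptides$exchangeable_amides <- vapply(seq_len(nrow(peptides)), function(i)
    length(.exchanging_residues(construct, peptides$start[i],
                                peptides$end[i])), integer(1))
  peptides <- peptides[peptides$exchangeable_amides >= 1L, , drop = FALSE]
  rownames(peptides) <- NULL
  structure(peptides, class = c("peptide_map", "data.frame"),
            construct = construct)
}

#' Noiseless expected uptake under the exchange model
#'
#' For peptide p at time t the expected deuterium uptake is
#' `(1-b) f_D [ sum_{j in p, non-EX1} (1 - exp(-(k_int_j/P_j) t))
#'  + sum_{EX1 segments s overlapping p} n_s (1 - exp(-k_op_s t)) ]`
#' where the sums run over exchanging residues (first residue and prolines
#' excluded) and n_s counts the exchanging residues of p inside segment s.
#'
#' @param model an [exchange_model()].
#' @param map a [generate_peptide_map()] result (or data.frame with
#'   `start`, `end`).
#' @param protocol a [labeling_protocol()].
#' @param state state name present in the model.
#' @param times exposure times (default: the protocol's).
#' @return Matrix (peptides x times) of expected uptake in Da.
#' @export
expected_uptake <- function(model, map, protocol, state,
                            times = protocol$times) {
  stopifnot(inherits(model, "exchange_model"),
            inherits(protocol, "labeling_protocol"))
  st <- model$states[[state]]
  if (is.null(st)) stop("state '", state, "' not present in model",
                        call. = FALSE)
  cs <- model$construct
  offset <- cs$offset
  amp <- (1 - protocol$back_exchange) * protocol$f_D
  out <- matrix(0, nrow = nrow(map), ncol = length(times),
                dimnames = list(NULL, paste0("t", times)))
  for (i in seq_len(nrow(map))) {
    ex <- .exchanging_residues(cs, map$start[i], map$end[i])
    in_ex1 <- rep(FALSE, length(ex))
    ex1_terms <- NULL
    if (!is.null(st$ex1)) {
      for (k in seq_len(nrow(st$ex1))) {
        seg <- ex >= st$ex1$start[k] & ex <= st$ex1$end[k]
        if (any(seg)) {
          in_ex1 <- in_ex1 | seg
          ex1_terms <- rbind(ex1_terms,
                             c(n = sum(seg), k_op = st$ex1$k_op[k]))
        }
      }
    }
    idx <- ex[!in_ex1] - offset + 1L
    rates <- model$k_int[idx] / st$protection[idx]
    for (ti in seq_along(times)) {
      t <- times[ti]
      u <- sum(1 - exp(-rates * t))
      if (!is.null(ex1_terms))
        u <- u + sum(ex1_terms[, "n"] * (1 - exp(-ex1_terms[, "k_op"] * t)))
      out[i, ti] <- amp * u
    }
  }
  out
}

#' Simulate a replicate peptide uptake table
#'
#' Produces a DynamX-cluster-style table: one row per peptide, exposure time
#' (including time 0) and replicate, with the measured centroid mass
#' `Center` = peptide average mass + expected uptake + Gaussian noise.
#' Byte-identical for a fixed protocol seed.
#'
#' @inheritParams expected_uptake
#' @return data.frame with columns `Protein`, `Start`, `End`, `Sequence`,
#'   `State`, `Exposure`, `Replicate`, `Center`.
#' @export
simulate_uptake <- function(model, map, protocol, state) {
  truth <- expected_uptake(model, map, protocol, state)
  cs <- model$construct
  base <- vapply(map$sequence, function(s) intact_mass(s), numeric(1),
                 USE.NAMES = FALSE)
  times <- c(0, protocol$times)
  truth <- cbind(0, truth)
  rows <- expand.grid(rep = seq_len(protocol$replicates),
                      ti = seq_along(times), pep = seq_len(nrow(map)))
  noise <- with_seed(protocol$seed + 1000L * match(state,
                                                   names(model$states)),
                     stats::rnorm(nrow(rows), 0, protocol$noise_sd))
  data.frame(
    Protein = cs$name,
    Start = map$start[rows$pep],
    End = map$end[rows$pep],
    Sequence = map$sequence[rows$pep],
    State = state,
    Exposure = times[rows$ti],
    Replicate = rows$rep,
    Center = base[rows$pep] + truth[cbind(rows$pep, rows$ti)] + noise,
    stringsAsFactors = FALSE
  )
}

# discrete convolution of two probability vectors on the 0..K grid
.dconv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# averagine-style Poisson natural isotopic envelope for a peptide mass
.natural_envelope <- function(mass, k_max = NULL) {
  lambda <- 5.34e-4 * mass
  if (is.null(k_max)) k_max <- max(3L, ceiling(lambda + 6 * sqrt(lambda) + 3))
  stats::dpois(0:k_max, lambda) / stats::ppois(k_max, lambda)
}

#' Simulate isotopic envelopes of one peptide over time
#'
#' The envelope at each exposure is the natural-abundance envelope
#' (averagine-style Poisson in the peptide mass) convolved with the
#' deuteration distribution on a 1-Da isotope grid. Under pure EX2 the
#' deuteration distribution is a single binomial over the exchangeable
#' amides with the mean site probability. When the peptide overlaps one EX1
#' segment, the result is a two-component mixture: a closed population
#' (EX1 residues unexchanged) of weight `exp(-k_op t)` and an open
#' population with the EX1 residues at the full labelling plateau.
#'
#' @inheritParams expected_uptake
#' @param peptide `c(start, end)` residue numbers, or a single-row of a
#'   peptide map.
#' @return List of class `envelope_series`; one `isotopic_envelope` per
#'   exposure time, each with fields `intensity` (normalised, isotope index
#'   0..K), `exposure`, `peptide`, `n_exchangeable`.
#' @export
simulate_envelopes <- function(model, peptide, protocol, state,
                               times = protocol$times) {
  stopifnot(inherits(model, "exchange_model"))
  if (is.data.frame(peptide)) peptide <- c(peptide$start[1], peptide$end[1])
  cs <- model$construct
  st <- model$states[[state]]
  if (is.null(st)) stop("state '", state, "' not present in model",
                        call. = FALSE)
  ex <- .exchanging_residues(cs, peptide[1], peptide[2])
  n_ex <- length(ex)
  if (n_ex < 1L) stop("peptide has no exchangeable amides", call. = FALSE)
  pep_seq <- paste(construct_residue(cs, peptide[1]:peptide[2]),
                   collapse = "")
  nat <- .natural_envelope(intact_mass(pep_seq))
  offset <- cs$offset
  amp <- (1 - protocol$back_exchange) * protocol$f_D
  in_ex1 <- rep(FALSE, n_ex)
  k_op <- NULL
  if (!is.null(st$ex1)) {
    hits <- 0L
    for (k in seq_len(nrow(st$ex1))) {
      seg <- ex >= st$ex1$start[k] & ex <= st$ex1$end[k]
      if (any(seg)) { hits <- hits + 1L; in_ex1 <- in_ex1 | seg
        k_op <- st$ex1$k_op[k] }
    }
    if (hits > 1L)
      stop("peptide overlaps more than one EX1 segment", call. = FALSE)
  }
  idx_non <- ex[!in_ex1] - offset + 1L
  n_non <- length(idx_non)
  n_e1 <- sum(in_ex1)
  rates <- model$k_int[idx_non] / st$protection[idx_non]
  out <- lapply(times, function(t) {
    p_non <- if (n_non) mean(amp * (1 - exp(-rates * t))) else 0
    closed <- if (n_non) stats::dbinom(0:n_non, n_non, p_non) else 1
    if (n_e1 > 0L) {
      w <- exp(-k_op * t)
      open_extra <- stats::dbinom(0:n_e1, n_e1, amp)
      deut <- w * c(closed, rep(0, n_e1)) + (1 - w) * .dconv(closed, open_extra)
    } else {
      deut <- closed
    }
    intensity <- .dconv(nat, deut)
    intensity <- intensity / sum(intensity)
    structure(list(intensity = intensity, exposure = t,
                   peptide = peptide, n_exchangeable = n_ex, natural = nat),
              class = "isotopic_envelope")
  })
  structure(out, class = "envelope_series", peptide = peptide,
            n_exchangeable = n_ex, times = times)
}

#' Intensity-weighted centroid of an isotopic envelope (isotope-index units)
#' @param envelope an `isotopic_envelope` (or bare intensity vector).
#' @return numeric scalar.
#' @export
envelope_centroid <- function(envelope) {
  y <- if (inherits(envelope, "isotopic_envelope")) envelope$intensity
       else envelope
  sum((seq_along(y) - 1) * y) / sum(y)
}
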