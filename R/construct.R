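#' Protein construct with region annotations and modifications
#'
#' A `construct` bundles a one-letter amino-acid sequence with its residue
#' numbering (the number of the first sequence position), named region
#' annotations (domains, motifs) and site modifications (phospho, acetyl).
#' Coordinates are 1-based inclusive residue numbers throughout, so a
#' construct covering "aa 1-722" has `offset = 1` and length 722.
#'
#' @param sequence character scalar, 1-letter codes of the 20 standard
#'   amino acids.
#' @param name construct label.
#' @param offset residue number of the first sequence position (default 1).
#' @param regions `NULL` or a data.frame with columns `label`, `start`, `end`.
#' @param modifications `NULL` or a data.frame with columns `kind`
#'   (`"phospho"` or `"acetyl"`) and `position`. Phospho sites must be S/T/Y;
#'   acetyl sites K (or the N-terminal residue).
#' @return An object of class `construct`.
#' @examples
#' cs <- construct("MSAESGPGTR", name = "toy")
#' intact_mass(cs)
#' @export
construct <- function(sequence, name = "construct", offset = 1L,
                      regions = NULL, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(.aa_avg))
  if (length(bad))
    stop("unknown residue code '", chars[bad[1L]], "' at sequence position ",
         bad[1L], call. = FALSE)
  offset <- as.integer(offset)
  last <- offset + length(chars) - 1L
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    stopifnot(all(c("label", "start", "end") %in% names(regions)))
    if (any(regions$start > regions$end))
      stop("region with start > end", call. = FALSE)
    if (any(regions$start < offset | regions$end > last))
      stop("region outside construct coordinates [", offset, ", ", last, "]",
           call. = FALSE)
  }
  if (!is.null(modifications)) {
    modifications <- as.data.frame(modifications)
    stopifnot(all(c("kind", "position") %in% names(modifications)))
    if (!all(modifications$kind %in% names(.mod_shifts)))
      stop("modification kind must be one of: ",
           paste(names(.mod_shifts), collapse = ", "), call. = FALSE)
    if (any(modifications$position < offset | modifications$position > last))
      stop("modification outside construct coordinates", call. = FALSE)
    res <- chars[modifications$position - offset + 1L]
    ph <- modifications$kind == "phospho"
    if (any(ph & !res %in% c("S", "T", "Y")))
      stop("phospho modification on non-S/T/Y residue", call. = FALSE)
    ac <- modifications$kind == "acetyl"
    if (any(ac & !(res == "K" | modifications$position == offset)))
      stop("acetyl modification on non-K, non-N-terminal residue",
           call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, offset = offset,
                 regions = regions, modifications = modifications),
            class = "construct")
}

#' @export
print.construct <- function(x, ...) {
  cat("<construct> ", x$name, ": residues ", x$offset, "-",
      x$offset + nchar(x$sequence) - 1L, " (", nchar(x$sequence), " aa)\n",
      sep = "")
  if (!is.null(x$regions))
    cat("  regions: ", paste0(x$regions$label, " [", x$regions$start, "-",
                              x$regions$end, "]", collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$modifications))
    cat("  modifications:", nrow(x$modifications), "\n")
  invisible(x)
}

#' @export
length.construct <- function(x) nchar(x$sequence)

# residues as character vector
.construct_chars <- function(x) strsplit(x$sequence, "")[[1]]

# residue at absolute position(s)
construct_residue <- function(x, position) {
  idx <- position - x$offset + 1L
  if (any(idx < 1L | idx > nchar(x$sequence)))
    stop("position outside construct", call. = FALSE)
  .construct_chars(x)[idx]
}

#' Extract a sub-construct by residue numbers
#'
#' @param x a [construct()].
#' @param start,end residue numbers, 1-based inclusive.
#' @return A `construct` covering `[start, end]`, keeping the numbering and
#'   any regions/modifications that fall entirely inside.
#' @export
construct_window <- function(x, start, end) {
  stopifnot(inherits(x, "construct"), start <= end)
  idx <- (start:end) - x$offset + 1L
  if (idx[1L] < 1L || idx[length(idx)] > nchar(x$sequence))
    stop("window outside construct", call. = FALSE)
  regions <- x$regions
  if (!is.null(regions))
    regions <- regions[regions$start >= start & regions$end <= end, ,
                       drop = FALSE]
  mods <- x$modifications
  if (!is.null(mods))
    mods <- mods[mods$position >= start & mods$position <= end, , drop = FALSE]
  if (!is.null(regions) && nrow(regions) == 0L) regions <- NULL
  if (!is.null(mods) && nrow(mods) == 0L) mods <- NULL
  construct(substr(x$sequence, idx[1L], idx[length(idx)]),
            name = paste0(x$name, "_", start, "-", end), offset = start,
            regions = regions, modifications = mods)
}

#' Intact mass of a construct
#'
#' Sum of residue masses plus one water (unless disabled) plus modification
#' shifts plus any adduct mass. Average-scale masses are conventionally
#' reported to 0.1 Da.
#'
#' @param x a [construct()] or a plain sequence string.
#' @param opts a [mass_options()] object.
#' @param ... passed to [mass_options()] as a shorthand (`scale`,
#'   `include_water`, `adduct`) when `opts` is missing.
#' @return Mass in Da (numeric scalar, unrounded).
#' @examples
#' intact_mass("G")                      # 75.07 Da free glycine
#' intact_mass("SA") - intact_mass("AA") # serine/alanine side-chain difference
#' @export
intact_mass <- function(x, opts = mass_options(...), ...) {
  stopifnot(inherits(opts, "mass_options"))
  if (is.character(x)) x <- construct(x)
  stopifnot(inherits(x, "construct"))
  m <- .sequence_mass(x$sequence, opts$scale)
  if (opts$include_water) m <- m + water_mass(opts$scale)
  if (!is.null(x$modifications) && nrow(x$modifications) > 0L) {
    shifts <- vapply(x$modifications$kind,
                     function(k) .mod_shifts[[k]][[opts$scale]], numeric(1))
    m <- m + sum(shifts)
  }
  m + opts$adduct
}

#' Scan for CK2 consensus phosphorylation sites
#'
#' Finds every position matching the casein kinase 2 substrate consensus
#' S/TxxE/D (S or T followed, three residues later, by E or D; the two
#' intervening residues are unconstrained). Overlapping matches are all
#' reported, sorted by position.
#'
#' @param x a [construct()] or sequence string.
#' @param offset residue number of the first position (ignored for
#'   constructs, which carry their own numbering).
#' @return data.frame with columns `position` and `residue` ("S" or "T");
#'   zero rows when nothing matches.
#' @examples
#' find_ck2_consensus("ASDDE")  # S at position 2 (E at position 5)
#' @export
find_ck2_consensus <- function(x, offset = 1L) {
  if (inherits(x, "construct")) {
    offset <- x$offset
    x <- x$sequence
  }
  chars <- strsplit(toupper(x), "")[[1]]
  n <- length(chars)
  if (n < 4L)
    return(data.frame(position = integer(), residue = character()))
  i <- seq_len(n - 3L)
  hit <- chars[i] %in% c("S", "T") & chars[i + 3L] %in% c("E", "D")
  data.frame(position = i[hit] + as.integer(offset) - 1L,
             residue = chars[i][hit])
}

#' Apply point substitutions to a construct
#'
#' @param x a [construct()].
#' @param positions residue numbers to substitute.
#' @param to replacement residues (recycled if scalar).
#' @param expected optional original residues; when supplied, each position is
#'   checked and a mismatch is an error.
#' @return A new `construct` with the same numbering. Modifications sitting on
#'   substituted positions are dropped if no longer chemically valid.
#' @examples
#' cs <- construct("ASDDE")
#' apply_substitutions(cs, 2, "A", expected = "S")
#' @export
apply_substitutions <- function(x, positions, to, expected = NULL) {
  stopifnot(inherits(x, "construct"))
  if (length(positions) == 0L) return(x)
  positions <- as.integer(positions)
  to <- toupper(rep_len(to, length(positions)))
  if (!all(to %in% names(.aa_avg)))
    stop("unknown replacement residue code", call. = FALSE)
  idx <- positions - x$offset + 1L
  if (any(idx < 1L | idx > nchar(x$sequence)))
    stop("substitution position ",
         positions[which(idx < 1L | idx > nchar(x$sequence))[1L]],
         " outside construct", call. = FALSE)
  chars <- .construct_chars(x)
  if (!is.null(expected)) {
    expected <- toupper(rep_len(expected, length(positions)))
    bad <- which(chars[idx] != expected)
    if (length(bad))
      stop("expected residue ", expected[bad[1L]], " at position ",
           positions[bad[1L]], " but found ", chars[idx[bad[1L]]],
           call. = FALSE)
  }
  chars[idx] <- to
  mods <- x$modifications
  if (!is.null(mods) && nrow(mods) > 0L) {
    newres <- chars[mods$position - x$offset + 1L]
    keep <- ifelse(mods$kind == "phospho", newres %in% c("S", "T", "Y"),
                   newres == "K" | mods$position == x$offset)
    mods <- mods[keep, , drop = FALSE]
    if (nrow(mods) == 0L) mods <- NULL
  }
  construct(paste(chars, collapse = ""), name = x$name, offset = x$offset,
            regions = x$regions, modifications = mods)
}

#' Replace a residue interval with a linker sequence
#'
#' Deletion-plus-linker constructs (e.g. replacing a coiled-coil segment with
#' a short glycine-serine linker) are modelled by excising `[start, end]` and
#' splicing in `linker`. Numbering keeps the original offset; region and
#' modification annotations are dropped because downstream coordinates change.
#'
#' @param x a [construct()].
#' @param start,end interval to delete (residue numbers, inclusive).
#' @param linker replacement sequence (may be `""` for a pure deletion).
#' @return A new `construct`.
#' @export
replace_region <- function(x, start, end, linker = "") {
  stopifnot(inherits(x, "construct"), start <= end)
  i1 <- start - x$offset + 1L
  i2 <- end - x$offset + 1L
  if (i1 < 1L || i2 > nchar(x$sequence))
    stop("interval outside construct", call. = FALSE)
  seq <- paste0(substr(x$sequence, 1L, i1 - 1L), toupper(linker),
                substr(x$sequence, i2 + 1L, nchar(x$sequence)))
  construct(seq, name = paste0(x$name, "_d", start, "-", end),
            offset = x$offset)
}

#' Heptad-repeat utilities for coiled-coil annotation
#'
#' `count_complete_heptads()` counts how many complete abcdefg heptads fit in
#' a residue interval: `floor(length / 7)`. `heptad_register_score()` scores
#' how coiled-coil-like an interval is: for each of the 7 possible register
#' phases, the fraction of a/d core positions occupied by hydrophobic
#' residues (A, I, L, M, F, V, W, Y); the best phase wins, ties broken by the
#' smallest phase index.
#'
#' @param start,end residue interval, 1-based inclusive.
#' @param x a [construct()] or sequence string (scoring only).
#' @return `count_complete_heptads()`: integer. `heptad_register_score()`:
#'   list with `register` (phase index 0-6, position of the first 'a') and
#'   `score` in \[0, 1\].
#' @examples
#' count_complete_heptads(506, 527)  # 22 residues -> 3 heptads
#' @export
count_complete_heptads <- function(start, end) {
  stopifnot(start <= end)
  as.integer((end - start + 1L) %/% 7L)
}

.hydrophobic <- c("A", "I", "L", "M", "F", "V", "W", "Y")

#' @rdname count_complete_heptads
#' @export
heptad_register_score <- function(x, start, end) {
  if (inherits(x, "construct")) {
    offset <- x$offset
    seq <- x$sequence
  } else {
    offset <- 1L
    seq <- toupper(x)
  }
  stopifnot(start <= end)
  i1 <- start - offset + 1L
  i2 <- end - offset + 1L
  if (i1 < 1L || i2 > nchar(seq))
    stop("interval outside sequence", call. = FALSE)
  chars <- strsplit(substr(seq, i1, i2), "")[[1]]
  n <- length(chars)
  best <- list(register = 0L, score = -1)
  for (phase in 0:6) {
    heptad_pos <- ((seq_len(n) - 1L + phase) %% 7L)  # 0 = 'a', 3 = 'd'
    core <- heptad_pos %in% c(0L, 3L)
    if (!any(core)) next
    score <- mean(chars[core] %in% .hydrophobic)
    if (score > best$score) best <- list(register = phase, score = score)
  }
  best
}

#' Read and write constructs as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O. `read_construct_fasta()` returns
#' a single [construct()] (the first record, or the one named by `which`).
#'
#' @param path FASTA file.
#' @param which optional record name.
#' @param offset residue number of the first position.
#' @param x a `construct` to write.
#' @return `read_construct_fasta()`: a `construct`;
#'   `write_construct_fasta()`: the path, invisibly.
#' @export
read_construct_fasta <- function(path, which = NULL, offset = 1L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  i <- 1L
  if (!is.null(which)) {
    i <- match(which, names(set))
    if (is.na(i)) stop("no FASTA record named '", which, "'", call. = FALSE)
  }
  construct(as.character(set[[i]]), name = names(set)[i], offset = offset)
}

#' @rdname read_construct_fasta
#' @export
write_construct_fasta <- function(x, path) {
  stopifnot(inherits(x, "construct"))
  set <- Biostrings::AAStringSet(x$sequence)
  names(set) <- x$name
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Packaged BRD4 sequence and region table
#'
#' `brd4_construct()` loads the packaged reconstruction of human BRD4
#' (UniProt O60885) residues 1-722 (the isoform-C span) together with the
#' study's region annotations; see the package vignette for the provenance
#' and validation of this reconstructed sequence. `brd4_regions()` returns
#' the region table alone.
#'
#' @param range optional `c(start, end)` residue window, e.g. `c(1, 530)`.
#' @return A [construct()] (or a data.frame for `brd4_regions()`).
#' @export
brd4_construct <- function(range = NULL) {
  fa <- system.file("extdata", "O60885_1-722_reconstructed.fasta",
                    package = "hdxdimer", mustWork = TRUE)
  regions <- brd4_regions()
  cs <- read_construct_fasta(fa)
  cs$name <- "BRD4_1-722"
  cs$regions <- regions
  cs <- construct(cs$sequence, name = cs$name, offset = 1L, regions = regions)
  if (!is.null(range)) {
    stopifnot(length(range) == 2L)
    cs <- construct_window(cs, range[1L], range[2L])
    cs$name <- paste0("BRD4_", range[1L], "-", range[2L])
  }
  cs
}

#' @rdname brd4_construct
#' @export
brd4_regions <- function() {
  path <- system.file("extdata", "brd4_regions.csv", package = "hdxdimer",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
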