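#' Fauchere-Pliska hydrophobicity scale
#'
#' Octanol/water side-chain transfer free energies (Fauchere & Pliska
#' 1983), the scale used by the Heliquest helical-wheel convention.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
fauchere_pliska <- function() {
  c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54, Q = -0.22,
    E = -0.64, G = 0.00, H = 0.13, I = 1.80, L = 1.70, K = -0.99,
    M = 1.23, F = 1.79, P = 0.72, S = -0.04, T = 0.26, W = 2.25,
    Y = 0.96, V = 1.22)
}

#' Construct a helix sequence
#'
#' @param sequence One-letter amino-acid string (20 standard residues
#'   only) or character vector of single letters; positions are 1-based.
#' @param name Sequence name.
#' @param hydrophobic_set Residues counted as hydrophobic. The default
#'   `{W, L, V, I, F, M}` is the set that drives helical-turn statistics
#'   of ALPS motifs; alanine and cysteine are deliberately excluded.
#' @param scale Hydrophobicity scale (named numeric over residues).
#' @return A `helix_sequence` object.
#' @examples
#' alps <- alps_peptide()
#' length(alps$residues)
#' @export
helix_sequence <- function(sequence, name = "peptide",
                           hydrophobic_set = c("W", "L", "V", "I",
                                               "F", "M"),
                           scale = fauchere_pliska()) {
  res <- if (length(sequence) == 1) {
    strsplit(toupper(sequence), "")[[1]]
  } else toupper(sequence)
  bad <- setdiff(unique(res), names(fauchere_pliska()))
  if (length(bad) > 0) {
    stop("nonstandard residue letter(s): ", paste(bad, collapse = ", "))
  }
  structure(list(residues = res, name = name,
                 hydrophobic_set = hydrophobic_set, scale = scale),
            class = "helix_sequence")
}

#' @export
print.helix_sequence <- function(x, ...) {
  cat(">", x$name, " (", length(x$residues), " aa)\n", sep = "")
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
as.character.helix_sequence <- function(x, ...) {
  paste(x$residues, collapse = "")
}

is_hydrophobic <- function(seq) {
  seq$residues %in% seq$hydrophobic_set
}

# ---- shipped sequences -----------------------------------------------

#' ALPS-motif sequence fixtures
#'
#' The synthetic-peptide form of the GMAP-210 ALPS motif (residues
#' 1-38, with the initiator methionine replaced by cysteine so that
#' peptide concentration can be read at 280 nm), its native form (M1),
#' the condensed variant condALPS in which polar residues between sparse
#' hydrophobic residues were deleted to create hydrophobic pairs, and
#' the two schematic spacing patterns (x rendered as serine): the
#' ALPS-like sparse `LxxxLxxxL` and the Arf1-like paired `IFxxLFxxLF`.
#'
#' @return A `helix_sequence`.
#' @name alps_sequences
NULL

#' @rdname alps_sequences
#' @export
alps_peptide <- function() {
  helix_sequence("CSSWLGGLGSGLGQSLGQVGGSLASLTGQISNFTKDML",
                 name = "ALPS-GMAP210-peptide")
}

#' @rdname alps_sequences
#' @export
alps_native <- function() {
  helix_sequence("MSSWLGGLGSGLGQSLGQVGGSLASLTGQISNFTKDML",
                 name = "ALPS-GMAP210-native")
}

#' @rdname alps_sequences
#' @export
cond_alps_peptide <- function() {
  helix_sequence("CSSWLGGLLGSLVGSLLTIFKDML", name = "condALPS-peptide")
}

#' @rdname alps_sequences
#' @export
pattern_sparse <- function() {
  helix_sequence("LSSSLSSSL", name = "sparse-LxxxLxxxL")
}

#' @rdname alps_sequences
#' @export
pattern_paired <- function() {
  helix_sequence("IFSSLFSSLF", name = "paired-IFxxLFxxLF")
}

#' Deletion positions that condense ALPS into condALPS
#'
#' The 14 polar positions (1-based, on the 38-aa peptide) whose removal
#' turns every sparse hydrophobic residue into a member of a hydrophobic
#' pair while retaining all hydrophobic residues, yielding the printed
#' 24-aa condALPS sequence.
#'
#' @return Integer vector of positions.
#' @export
alps_condensation_deletions <- function() {
  c(9L, 10L, 11L, 14L, 17L, 18L, 21L, 24L, 25L, 28L, 29L, 31L, 32L, 34L)
}

# ---- wheel / moment --------------------------------------------------

#' Hydrophobic moment and helical wheel
#'
#' Places residue `j` at angle `(j - 1) * 100` degrees around an ideal
#' alpha-helix (3.6 residues per turn) and computes the mean
#' hydrophobicity `<H>` and the Eisenberg hydrophobic moment
#' `muH = |sum_j h_j exp(i * j * delta)| / N` under the sequence's
#' scale. `muH` is invariant under sequence reversal (the phasor sum is
#' conjugated, preserving its magnitude), which is why an inverted ALPS
#' motif keeps its amphipathic character.
#'
#' @param seq A `helix_sequence` of length >= 2.
#' @return A `wheel_projection`: `mu_h`, `mean_h`, `direction_deg`
#'   (azimuth of the moment), `angles_deg` (per-residue wheel angles),
#'   `h` (per-residue hydrophobicities).
#' @export
hydrophobic_moment <- function(seq) {
  stopifnot(inherits(seq, "helix_sequence"))
  n <- length(seq$residues)
  if (n < 2) stop("sequence must have length >= 2")
  h <- unname(seq$scale[seq$residues])
  if (anyNA(h)) stop("scale lacks values for some residues")
  delta <- 100 * pi / 180
  ang <- (seq_len(n) - 1) * delta
  s <- sum(h * exp(1i * ang))
  structure(list(mu_h = Mod(s) / n, mean_h = mean(h),
                 direction_deg = (Arg(s) * 180 / pi) %% 360,
                 angles_deg = (ang * 180 / pi) %% 360, h = h,
                 name = seq$name), class = "wheel_projection")
}

#' @export
print.wheel_projection <- function(x, ...) {
  cat("Helical wheel of ", x$name, ": muH = ", signif(x$mu_h, 4),
      ", <H> = ", signif(x$mean_h, 4), ", direction = ",
      round(x$direction_deg, 1), " deg\n", sep = "")
  invisible(x)
}

# ---- turns -----------------------------------------------------------

#' Partition a sequence into helical turns
#'
#' Turn `k` of an ideal alpha-helix (3.6 residues per turn) spans
#' positions `floor(3.6 * (k - 1)) + 1` through `floor(3.6 * k)`; the
#' turns tile `1..N` without gaps or overlaps and the last turn is
#' clipped at `N`.
#'
#' @param seq A `helix_sequence`.
#' @return Data frame with `turn`, `start`, `end`, `n_hydrophobic`.
#' @export
partition_turns <- function(seq) {
  stopifnot(inherits(seq, "helix_sequence"))
  n <- length(seq$residues)
  if (n < 1) stop("sequence must have length >= 1")
  k <- seq_len(ceiling(n / 3.6))
  start <- floor(3.6 * (k - 1)) + 1
  end <- pmin(floor(3.6 * k), n)
  hyd <- is_hydrophobic(seq)
  data.frame(turn = k, start = start, end = end,
             n_hydrophobic = vapply(
               k, function(i) sum(hyd[start[i]:end[i]]), integer(1)))
}

#' Count turns with exactly one hydrophobic residue
#'
#' The single-hydrophobic-per-turn statistic that distinguishes
#' sparse ALPS-type helices (for native GMAP-210 ALPS: 9 of its 11
#' turns) from Arf/Sar-type helices with hydrophobic doublets.
#'
#' @param seq A `helix_sequence`.
#' @return Integer count.
#' @export
count_single_hydrophobic_turns <- function(seq) {
  sum(partition_turns(seq)$n_hydrophobic == 1L)
}

# ---- spacing ---------------------------------------------------------

#' Sparse/paired hydrophobic spacing profile
#'
#' The paired fraction is the fraction of hydrophobic residues with a
#' sequence-adjacent hydrophobic neighbor. Classification thresholds:
#' `sparse` below 0.25, `paired` above 0.75, `mixed` in between.
#'
#' @param seq A `helix_sequence`.
#' @param sparse_below,paired_above Classification thresholds.
#' @return A `spacing_profile`: `hydrophobic_positions`,
#'   `paired_fraction`, `classification`, `status` (`"ok"`, or
#'   `"undefined"` when the sequence has no hydrophobic residue).
#' @export
spacing_profile <- function(seq, sparse_below = 0.25,
                            paired_above = 0.75) {
  stopifnot(inherits(seq, "helix_sequence"))
  hyd <- is_hydrophobic(seq)
  pos <- which(hyd)
  if (length(pos) == 0) {
    return(structure(list(hydrophobic_positions = integer(0),
                          paired_fraction = NA_real_,
                          classification = NA_character_,
                          status = "undefined"),
                     class = "spacing_profile"))
  }
  paired <- ((pos - 1) %in% pos) | ((pos + 1) %in% pos)
  pf <- mean(paired)
  cls <- if (pf < sparse_below) "sparse"
  else if (pf > paired_above) "paired"
  else "mixed"
  structure(list(hydrophobic_positions = pos, paired_fraction = pf,
                 classification = cls, status = "ok"),
            class = "spacing_profile")
}

#' @export
print.spacing_profile <- function(x, ...) {
  if (x$status != "ok") {
    cat("Spacing profile: undefined (no hydrophobic residues)\n")
  } else {
    cat("Spacing profile:", x$classification, "(paired fraction",
        signif(x$paired_fraction, 3), "over",
        length(x$hydrophobic_positions), "hydrophobic residues)\n")
  }
  invisible(x)
}

# ---- transformations -------------------------------------------------

#' Invert (reverse) a sequence
#'
#' Reads the sequence from the C terminus to the N terminus. The residue
#' composition, mean hydrophobicity and hydrophobic moment are exactly
#' preserved, while the positional identity to the original is typically
#' low: inversion scrambles any stereospecific reading of the sequence
#' without touching its amphipathic physics.
#'
#' @param seq A `helix_sequence`.
#' @return The reversed `helix_sequence`, name suffixed `"-inv"`.
#' @export
invert <- function(seq) {
  stopifnot(inherits(seq, "helix_sequence"))
  out <- seq
  out$residues <- rev(seq$residues)
  out$name <- paste0(seq$name, "-inv")
  out
}

#' Condense a sequence by deleting polar positions
#'
#' Deletes the given (1-based) positions and renumbers the remainder.
#' Deleting a hydrophobic residue is refused: condensation must retain
#' every hydrophobic residue of the wild-type sequence. The attached
#' report flags any hydrophobic residue that still lacks an adjacent
#' hydrophobic neighbor after condensation.
#'
#' @param seq A `helix_sequence`.
#' @param deletion_positions Integer positions to delete.
#' @return Condensed `helix_sequence` (name suffixed `"-cond"`) with
#'   attribute `"condense_report"`.
#' @export
condense <- function(seq, deletion_positions) {
  stopifnot(inherits(seq, "helix_sequence"))
  pos <- unique(as.integer(deletion_positions))
  n <- length(seq$residues)
  if (length(pos) == 0) return(seq)
  if (any(pos < 1 | pos > n)) stop("deletion positions out of range 1..", n)
  hyd <- is_hydrophobic(seq)
  offending <- pos[hyd[pos]]
  if (length(offending) > 0) {
    stop("refusing to delete hydrophobic residue(s) at position(s) ",
         paste(offending, collapse = ", "),
         ": condensation must retain all hydrophobic residues")
  }
  out <- seq
  out$residues <- seq$residues[-pos]
  out$name <- paste0(seq$name, "-cond")
  sp <- spacing_profile(out)
  unpaired <- if (sp$status == "ok") {
    p <- sp$hydrophobic_positions
    p[!(((p - 1) %in% p) | ((p + 1) %in% p))]
  } else integer(0)
  attr(out, "condense_report") <- list(
    deleted = sort(pos), still_sparse_positions = unpaired,
    all_paired = length(unpaired) == 0)
  out
}

# ---- edits -----------------------------------------------------------

parse_edit <- function(e) {
  if (grepl("^[A-Z][0-9]+[A-Z]$", e)) {
    list(op = "sub", from = substr(e, 1, 1),
         pos = as.integer(substr(e, 2, nchar(e) - 1)),
         to = substr(e, nchar(e), nchar(e)))
  } else if (grepl("^Ins[0-9]+[A-Z]+$", e)) {
    m <- regmatches(e, regexec("^Ins([0-9]+)([A-Z]+)$", e))[[1]]
    list(op = "ins", pos = as.integer(m[2]), aa = m[3])
  } else if (grepl("^Del[0-9]+-[0-9]+$", e)) {
    m <- regmatches(e, regexec("^Del([0-9]+)-([0-9]+)$", e))[[1]]
    list(op = "del", from_pos = as.integer(m[2]),
         to_pos = as.integer(m[3]))
  } else {
    stop("unparseable edit '", e, "'; use forms like \"L12D\", ",
         "\"Ins20AA\", \"Del7-28\"")
  }
}

#' Apply point mutations, insertions and deletions
#'
#' Edits are strings applied left to right, positions referring to the
#' sequence state at the time each edit is applied:
#' * `"L12D"` — substitute; the stated wild-type letter must match the
#'   current residue at that position (guards 1-based bookkeeping),
#' * `"Ins20AA"` — insert `AA` after position 20,
#' * `"Del7-28"` — delete positions 7..28 (truncations are expressed as
#'   kept intervals via [truncate_helix()]).
#'
#' @param seq A `helix_sequence`.
#' @param edits Character vector of edit strings.
#' @return Edited `helix_sequence` with attribute `"edit_log"` (a data
#'   frame recording each edit and the material needed to undo it).
#' @seealso [invert_edit_log()] for round-tripping.
#' @export
mutate_helix <- function(seq, edits) {
  stopifnot(inherits(seq, "helix_sequence"))
  res <- seq$residues
  log <- list()
  for (e in edits) {
    ed <- parse_edit(e)
    if (ed$op == "sub") {
      if (ed$pos < 1 || ed$pos > length(res)) {
        stop("substitution position ", ed$pos, " out of range")
      }
      if (res[ed$pos] != ed$from) {
        stop("wild-type mismatch at position ", ed$pos, ": edit '", e,
             "' expects ", ed$from, " but sequence has ", res[ed$pos])
      }
      res[ed$pos] <- ed$to
      log[[length(log) + 1]] <- data.frame(edit = e, op = "sub",
                                           removed = ed$from)
    } else if (ed$op == "ins") {
      if (ed$pos < 0 || ed$pos > length(res)) {
        stop("insertion position ", ed$pos, " out of range")
      }
      ins <- strsplit(ed$aa, "")[[1]]
      res <- append(res, ins, after = ed$pos)
      log[[length(log) + 1]] <- data.frame(edit = e, op = "ins",
                                           removed = "")
    } else {
      if (ed$from_pos < 1 || ed$to_pos > length(res) ||
          ed$from_pos > ed$to_pos) {
        stop("deletion range ", ed$from_pos, "-", ed$to_pos, " invalid")
      }
      removed <- paste(res[ed$from_pos:ed$to_pos], collapse = "")
      res <- res[-(ed$from_pos:ed$to_pos)]
      log[[length(log) + 1]] <- data.frame(edit = e, op = "del",
                                           removed = removed)
    }
  }
  out <- helix_sequence(res, name = paste0(seq$name, "-mut"),
                        hydrophobic_set = seq$hydrophobic_set,
                        scale = seq$scale)
  attr(out, "edit_log") <- do.call(rbind, log)
  out
}

#' Truncate to kept intervals
#'
#' Expresses a truncation series entry such as `[1-6/29-38]` as the
#' deletions of everything outside the kept intervals.
#'
#' @param seq A `helix_sequence`.
#' @param keep List of `c(start, end)` intervals (1-based, ascending,
#'   non-overlapping).
#' @return Truncated `helix_sequence` with edit log.
#' @export
truncate_helix <- function(seq, keep) {
  n <- length(seq$residues)
  keep_pos <- sort(unique(unlist(lapply(keep, function(iv) iv[1]:iv[2]))))
  if (any(keep_pos < 1 | keep_pos > n)) stop("kept interval out of range")
  drop <- setdiff(seq_len(n), keep_pos)
  if (length(drop) == 0) return(seq)
  # contiguous runs of dropped positions, applied from the right so that
  # positions keep their meaning
  runs <- split(drop, cumsum(c(1, diff(drop) != 1)))
  edits <- vapply(rev(runs), function(r) {
    paste0("Del", min(r), "-", max(r))
  }, character(1))
  out <- mutate_helix(seq, edits)
  out$name <- paste0(seq$name, "-trunc")
  out
}

#' Invert an edit log
#'
#' Produces the edit strings that undo a [mutate_helix()] log when
#' applied (in the returned order) to the edited sequence.
#'
#' @param log The `"edit_log"` attribute of an edited sequence.
#' @return Character vector of inverse edits.
#' @export
invert_edit_log <- function(log) {
  inv <- character(0)
  for (i in rev(seq_len(nrow(log)))) {
    e <- parse_edit(log$edit[i])
    inv <- c(inv, switch(log$op[i],
      sub = paste0(e$to, e$pos, log$removed[i]),
      ins = paste0("Del", e$pos + 1, "-", e$pos + nchar(e$aa)),
      del = paste0("Ins", e$from_pos - 1, log$removed[i])))
  }
  inv
}

# ---- comparison ------------------------------------------------------

#' Position-by-position sequence identity
#'
#' Strict positional comparison of two equal-length sequences; no
#' alignment is performed.
#'
#' @param a,b `helix_sequence` objects of equal length.
#' @return List with `matches`, `mismatches`, `identity`.
#' @export
positional_identity <- function(a, b) {
  stopifnot(inherits(a, "helix_sequence"), inherits(b, "helix_sequence"))
  if (length(a$residues) != length(b$residues)) {
    stop("sequences have different lengths (", length(a$residues),
         " vs ", length(b$residues), "); no alignment is performed")
  }
  m <- sum(a$residues == b$residues)
  n <- length(a$residues)
  list(matches = m, mismatches = n - m, identity = m / n)
}

# ---- FASTA -----------------------------------------------------------

#' Read/write helix sequences as FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O.
#'
#' @param seqs A `helix_sequence` or list of them.
#' @param path File path.
#' @return `write_helix_fasta` returns `path` invisibly;
#'   `read_helix_fasta` returns a named list of `helix_sequence`.
#' @export
write_helix_fasta <- function(seqs, path) {
  if (inherits(seqs, "helix_sequence")) seqs <- list(seqs)
  ss <- Biostrings::AAStringSet(
    vapply(seqs, as.character, character(1)))
  names(ss) <- vapply(seqs, function(s) s$name, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_helix_fasta
#' @export
read_helix_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    helix_sequence(as.character(ss[[i]]), name = names(ss)[i])
  })
  stats::setNames(out, names(ss))
}
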