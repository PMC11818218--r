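# Sequence windows are 21-character strings, offsets -10..+10 with the
# modified residue at the center; "_" pads beyond protein termini and never
# counts as a residue in any frequency.

WINDOW_FLANK <- 10L
WINDOW_WIDTH <- 2L * WINDOW_FLANK + 1L

#' Extract +/-10 residue windows around modification sites
#'
#' For each site, takes the 10 residues up- and downstream of the modified
#' position (center = the modified residue), padding with `_` where the
#' window runs past a protein terminus. Sites whose declared residue does not
#' match the sequence at that position are skipped with a warning — this
#' guards against off-by-one coordinate errors.
#'
#' @param seqs named character vector protein_id -> sequence ([read_fasta]).
#' @param sites tibble with `site_id`, `protein_id`, `position`, `residue`
#'   (e.g. the `meta` of a [site_table]).
#' @return tibble: `site_id`, `window` (21 characters).
#' @export
extract_windows <- function(seqs, sites) {
  seq_of <- seqs[sites$protein_id]
  n_miss <- sum(is.na(seq_of))
  if (n_miss) warning(n_miss, " site(s) on proteins absent from FASTA skipped")
  keep <- !is.na(seq_of)
  sites <- sites[keep, , drop = FALSE]
  seq_of <- seq_of[keep]
  at <- substr(seq_of, sites$position, sites$position)
  bad <- at != sites$residue
  if (any(bad))
    warning(sum(bad), " site(s) with residue mismatch at stated position skipped")
  sites <- sites[!bad, , drop = FALSE]
  seq_of <- seq_of[!bad]
  win <- vapply(seq_along(seq_of), function(i)
    window_at(seq_of[i], sites$position[i]), character(1))
  tibble::tibble(site_id = sites$site_id, window = win)
}

window_at <- function(seq, pos) {
  n <- nchar(seq)
  lo <- pos - WINDOW_FLANK; hi <- pos + WINDOW_FLANK
  core <- substr(seq, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - n)))
}

#' Background windows: all potential modification sites in the proteome
#'
#' One window per occurrence of `residue` in every supplied sequence — the
#' null model against which foreground windows are scored.
#'
#' @param seqs named character vector protein_id -> sequence.
#' @param residue the modifiable residue (default `"K"`).
#' @return tibble: `site_id` (`<protein>_<residue><pos>`), `window`.
#' @export
build_background <- function(seqs, residue = "K") {
  per_prot <- lapply(names(seqs), function(p) {
    pos <- which(strsplit(seqs[[p]], "")[[1]] == residue)
    if (!length(pos)) return(NULL)
    tibble::tibble(site_id = paste0(p, "_", residue, pos),
                   window = vapply(pos, function(q) window_at(seqs[[p]], q),
                                   character(1)))
  })
  out <- do.call(rbind, per_prot)
  if (is.null(out))
    out <- tibble::tibble(site_id = character(), window = character())
  out
}

# windows (character vector) -> n x 21 character matrix
window_matrix <- function(windows) {
  if (!length(windows)) return(matrix(character(0), 0, WINDOW_WIDTH))
  stopifnot(all(nchar(windows) == WINDOW_WIDTH))
  matrix(unlist(strsplit(windows, ""), use.names = FALSE),
         ncol = WINDOW_WIDTH, byrow = TRUE)
}

#' Binomial upper-tail probability P(X >= k)
#'
#' The motif significance score: the chance of seeing at least `k` of `n`
#' foreground windows carry a residue whose background frequency is `p`.
#'
#' @param k observed count. @param n trials. @param p background frequency.
#' @return upper-tail probability.
#' @export
binom_tail <- function(k, n, p) stats::pbinom(k - 1, n, p, lower.tail = FALSE)

#' Iterative motif discovery (motif-x style)
#'
#' Greedy fix-and-reduce: at each step, every (offset != 0, residue) pair is
#' scored by the binomial tail P(X >= k_fg) with success probability equal to
#' the residue's frequency at that offset among the background windows still
#' matching the current partial motif (pads excluded from numerator and
#' denominator). The most significant pair is fixed if its p is below
#' `p_threshold` and its foreground count is at least `min_occ`; foreground
#' and background are then reduced to windows matching the fixed residue and
#' the step repeats. When no pair qualifies, the motif (if any position was
#' fixed) is emitted, its matching foreground windows are removed from the
#' pool, the background is restored in full, and the search restarts.
#' Ties in minimal p are broken by smaller |offset| then alphabetical
#' residue.
#'
#' @param fg foreground windows: character vector or tibble with `window`.
#' @param bg background windows: character vector or tibble with `window`.
#' @param p_threshold binomial significance threshold per fixed position
#'   (default 1e-6).
#' @param min_occ minimum foreground windows supporting a motif (default 20).
#' @param center letter rendered at the motif center (default `"K"`).
#' @return tibble, one row per motif: `pattern` (21-slot, `.` wildcards),
#'   `motif` (colon rendering, e.g. `"Kmal:C"` = C at +2), `fg_matches`,
#'   `bg_matches`, `fold_increase`, `n_fixed`, and a `steps` list-column of
#'   per-fix records (`offset`, `residue`, `p`, `fg_count`).
#' @export
motif_discovery <- function(fg, bg, p_threshold = 1e-6, min_occ = 20L,
                            center = "K") {
  fg <- if (is.data.frame(fg)) fg$window else fg
  bg <- if (is.data.frame(bg)) bg$window else bg
  if (!length(bg)) stop("empty background window set")
  fg_m <- window_matrix(fg)
  bg_m <- window_matrix(bg)
  n_fg_total <- nrow(fg_m)
  offsets <- setdiff(seq_len(WINDOW_WIDTH), WINDOW_FLANK + 1L)
  motifs <- list()
  pool <- fg_m
  repeat {
    if (!nrow(pool)) break
    cur_fg <- pool
    cur_bg <- bg_m
    fixed <- list()
    repeat {
      best <- NULL
      for (j in offsets) {
        if (any(vapply(fixed, function(f) f$col == j, logical(1)))) next
        fg_col <- cur_fg[, j]
        bg_col <- cur_bg[, j]
        n_fg <- sum(fg_col != "_")
        n_bg <- sum(bg_col != "_")
        if (n_fg == 0 || n_bg == 0) next
        fg_tab <- table(fg_col[fg_col != "_"])
        for (res in names(fg_tab)) {
          k <- fg_tab[[res]]
          if (k < min_occ) next
          f_bg <- sum(bg_col == res) / n_bg
          p <- binom_tail(k, n_fg, f_bg)
          if (p >= p_threshold) next
          cand <- list(col = j, offset = j - (WINDOW_FLANK + 1L),
                       residue = res, p = p, k = k)
          if (is.null(best) || p < best$p ||
              (p == best$p && (abs(cand$offset) < abs(best$offset) ||
                               (abs(cand$offset) == abs(best$offset) &&
                                res < best$residue))))
            best <- cand
        }
      }
      if (is.null(best)) break
      fixed[[length(fixed) + 1L]] <- best
      cur_fg <- cur_fg[cur_fg[, best$col] == best$residue, , drop = FALSE]
      cur_bg <- cur_bg[cur_bg[, best$col] == best$residue, , drop = FALSE]
    }
    if (!length(fixed)) break
    pattern <- rep(".", WINDOW_WIDTH)
    pattern[WINDOW_FLANK + 1L] <- center
    for (f in fixed) pattern[f$col] <- f$residue
    matched <- matches_pattern(pool, fixed)
    motifs[[length(motifs) + 1L]] <- tibble::tibble(
      pattern = paste(pattern, collapse = ""),
      motif = render_motif(fixed, center = center),
      fg_matches = nrow(cur_fg),
      bg_matches = nrow(cur_bg),
      fold_increase = (nrow(cur_fg) / n_fg_total) /
        max(nrow(cur_bg) / nrow(bg_m), .Machine$double.xmin),
      n_fixed = length(fixed),
      steps = list(tibble::tibble(
        offset = vapply(fixed, `[[`, numeric(1), "offset"),
        residue = vapply(fixed, `[[`, character(1), "residue"),
        p = vapply(fixed, `[[`, numeric(1), "p"),
        fg_count = vapply(fixed, `[[`, numeric(1), "k"))))
    pool <- pool[!matched, , drop = FALSE]
  }
  if (!length(motifs))
    return(tibble::tibble(pattern = character(), motif = character(),
                          fg_matches = integer(), bg_matches = integer(),
                          fold_increase = numeric(), n_fixed = integer(),
                          steps = list()))
  do.call(rbind, motifs)
}

matches_pattern <- function(m, fixed) {
  ok <- rep(TRUE, nrow(m))
  for (f in fixed) ok <- ok & m[, f$col] == f$residue
  ok
}

# colon rendering: "Kmal:::C" means C at offset +4 (colons are wildcards)
render_motif <- function(fixed, center = "K") {
  offs <- vapply(fixed, `[[`, numeric(1), "offset")
  res <- vapply(fixed, `[[`, character(1), "residue")
  left <- ""
  if (any(offs < 0)) {
    lo <- min(offs)
    slots <- rep(":", -lo)
    for (i in which(offs < 0)) slots[offs[i] - lo + 1L] <- res[i]
    left <- paste(slots, collapse = "")
  }
  right <- ""
  if (any(offs > 0)) {
    hi <- max(offs)
    slots <- rep(":", hi)
    for (i in which(offs > 0)) slots[offs[i]] <- res[i]
    right <- paste(slots, collapse = "")
  }
  paste0(left, center, "mal", right)
}

#' Position-residue enrichment heatmap around the modified residue
#'
#' For every amino acid and offset (-10..-1, +1..+10), the log2 ratio of
#' foreground to background relative frequency, with a pseudo-count so
#' entries stay finite. Pads are excluded from numerators and denominators.
#' Positive entries mean enrichment around modified sites, negative mean
#' depletion.
#'
#' @param fg,bg windows (character vector or tibble with `window`).
#' @param epsilon pseudo-count added per (residue, offset) cell (default 0.5).
#' @return 20 x 20 numeric matrix, rows = residues, columns = offsets.
#' @export
frequency_heatmap <- function(fg, bg, epsilon = 0.5) {
  fg <- if (is.data.frame(fg)) fg$window else fg
  bg <- if (is.data.frame(bg)) bg$window else bg
  fg_m <- window_matrix(fg)
  bg_m <- window_matrix(bg)
  offsets <- setdiff(-WINDOW_FLANK:WINDOW_FLANK, 0L)
  out <- matrix(NA_real_, length(AA_ALPHABET), length(offsets),
                dimnames = list(AA_ALPHABET,
                                ifelse(offsets > 0, paste0("+", offsets),
                                       offsets)))
  n_aa <- length(AA_ALPHABET)
  for (idx in seq_along(offsets)) {
    j <- offsets[idx] + WINDOW_FLANK + 1L
    fg_col <- fg_m[, j]; fg_col <- fg_col[fg_col != "_"]
    bg_col <- bg_m[, j]; bg_col <- bg_col[bg_col != "_"]
    for (res in AA_ALPHABET) {
      f_fg <- (sum(fg_col == res) + epsilon) / (length(fg_col) + n_aa * epsilon)
      f_bg <- (sum(bg_col == res) + epsilon) / (length(bg_col) + n_aa * epsilon)
      out[res, idx] <- log2(f_fg / f_bg)
    }
  }
  out
}
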