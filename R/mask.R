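#' Per-column conservation profile of an alignment
#'
#' For each column, the most commonly observed non-gap character and its
#' fraction of all sequences (the denominator counts every row, so gaps
#' lower the fraction without being candidates).  A column is conserved when
#' the fraction strictly exceeds `conserved_frac`: a character present in
#' exactly 50% of the sequences does not qualify under the default.
#'
#' @param aln character matrix (rows = sequences, columns = sites) over
#'   `{A,C,G,T,IUPAC,N,-}`.
#' @param conserved_frac strict-majority threshold.
#' @return data.frame with one row per column: `common` (NA for all-gap
#'   columns), `fraction` and `conserved`.
#' @export
profile_sites <- function(aln, conserved_frac = 0.5) {
  stopifnot(is.matrix(aln), nrow(aln) >= 1L)
  n <- nrow(aln)
  L <- ncol(aln)
  common <- character(L)
  fraction <- numeric(L)
  for (j in seq_len(L)) {
    col <- aln[, j]
    col <- col[col != "-"]
    if (!length(col)) {
      common[j] <- NA_character_
      fraction[j] <- NA_real_
      next
    }
    tab <- sort(table(col), decreasing = TRUE)
    # deterministic tie-break: alphabetical among equally common characters
    top <- sort(names(tab)[tab == tab[1]])[1]
    common[j] <- top
    fraction[j] <- tab[[top]] / n
  }
  data.frame(common = common, fraction = fraction,
             conserved = !is.na(fraction) & fraction > conserved_frac,
             stringsAsFactors = FALSE)
}

#' Mask divergent or misaligned sequence regions
#'
#' Each sequence is scanned with windows of `window` consecutive conserved
#' columns (stride one conserved column).  A window passes for a sequence
#' when the sequence matches the common base at `min_match` or more of those
#' conserved columns; a gap at a conserved column counts as a mismatch.  A
#' character is masked (replaced by `mask_char`) when it lies within the
#' alignment-column span of at least one failing window and within the span
#' of no passing window; a character escapes masking as soon as one window
#' covering it passes.  The first window's span extends to the first
#' alignment column and the last window's span to the last column, so
#' unanchored edge regions beyond the conserved core are governed by the
#' nearest window rather than escaping the scan.  Gaps are never altered.
#' Alignments with fewer than
#' `window` conserved columns are evaluated per sequence over all available
#' conserved columns with the proportional threshold `min_match/window`; a
#' failing sequence is masked entirely.
#'
#' @param aln character matrix.
#' @param profile result of [profile_sites()] on `aln`.
#' @param window window length in conserved columns (default 20).
#' @param min_match pass threshold (default 10).
#' @param mask_char masking character (default `"N"`, which is gap-distinct
#'   so the downstream site filter can count it as non-base).
#' @return the masked matrix.
#' @export
mask_sequence_regions <- function(aln, profile, window = 20L, min_match = 10L,
                                  mask_char = "N") {
  stopifnot(nrow(aln) >= 1L, nrow(profile) == ncol(aln))
  cc <- which(profile$conserved)
  ncc <- length(cc)
  out <- aln
  if (ncc == 0L) return(out)
  common <- profile$common
  if (ncc < window) {
    for (r in seq_len(nrow(aln))) {
      frac <- sum(aln[r, cc] == common[cc]) / ncc
      if (frac < min_match / window) {
        row <- out[r, ]
        row[row != "-"] <- mask_char
        out[r, ] <- row
      }
    }
    return(out)
  }
  nw <- ncc - window + 1L
  cols <- seq_len(ncol(aln))
  # window w spans alignment columns cc[w] .. cc[w + window - 1], with the
  # first span stretched to column 1 and the last to the final column;
  # hi = last window starting at or before column j, lo = first window ending
  # at or after column j (both clamped so every column is covered)
  hi <- pmin(pmax(findInterval(cols, cc), 1L), nw)
  lo <- pmin(pmax(findInterval(cols - 1L, cc[window:ncc]) + 1L, 1L), nw)
  for (r in seq_len(nrow(aln))) {
    hit <- as.integer(aln[r, cc] == common[cc])
    cs <- cumsum(c(0L, hit))
    pass <- (cs[(window + 1L):(ncc + 1L)] - cs[1:nw]) >= min_match
    cp <- cumsum(c(0L, pass))
    any_pass <- (cp[hi + 1L] - cp[lo]) > 0L
    to_mask <- !any_pass & aln[r, ] != "-"
    if (any(to_mask)) out[r, to_mask] <- mask_char
  }
  out
}

#' Remove thin alignment sites
#'
#' Drops every column whose count of unmasked bases — characters that are
#' neither gaps, nor the mask character, nor missing (`?`) — is below
#' `min_unmasked`.
#'
#' @param aln character matrix (typically after masking).
#' @param min_unmasked minimum unmasked bases per retained column.
#' @param mask_char the masking character.
#' @return list with `alignment` (possibly 0-column), `kept` (old column
#'   indices retained, in order) and `dropped` (TRUE when no column
#'   survived).
#' @export
drop_thin_sites <- function(aln, min_unmasked = 23L, mask_char = "N") {
  unmasked <- colSums(!(aln == "-" | aln == mask_char | aln == "?"))
  kept <- which(unmasked >= min_unmasked)
  list(alignment = aln[, kept, drop = FALSE],
       kept = kept,
       dropped = length(kept) == 0L)
}

#' Trim one locus alignment: profile, mask, drop
#'
#' Applies [profile_sites()], [mask_sequence_regions()] and
#' [drop_thin_sites()] exactly once, in that order, then drops the locus if
#' the trimmed alignment is shorter than `params$min_final_length` columns.
#'
#' @param aln character matrix.
#' @param params a [pipeline_params()].
#' @return list with `alignment` (NULL when dropped), `kept` column map,
#'   `n_masked` (characters newly masked) and `dropped`.
#' @export
trim_locus <- function(aln, params = pipeline_params()) {
  prof <- profile_sites(aln, params$conserved_site_frac)
  masked <- mask_sequence_regions(aln, prof, params$mask_window,
                                  params$mask_min_matches)
  n_masked <- sum(masked == "N" & aln != "N")
  thin <- drop_thin_sites(masked, resolve_min_unmasked(params, nrow(aln)))
  dropped <- thin$dropped || ncol(thin$alignment) < params$min_final_length
  list(alignment = if (dropped) NULL else thin$alignment,
       kept = thin$kept,
       n_masked = n_masked,
       dropped = dropped)
}

#' Read and write aligned FASTA
#'
#' @param path FASTA path.
#' @return character matrix with taxon rownames.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty alignment: ", path)
  m <- do.call(rbind, strsplit(toupper(as.character(x)), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' @rdname read_alignment_fasta
#' @param aln character matrix with rownames.
#' @export
write_alignment_fasta <- function(aln, path) {
  x <- Biostrings::BStringSet(apply(aln, 1L, paste, collapse = ""))
  names(x) <- rownames(aln)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
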