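`%||%` <- function(a, b) if (is.null(a)) b else a

# circular distance from position a forward to position b on a replicon of
# length L; 0 <= result < L
circ_dist <- function(from, to, L) {
  ((to - from) %% L + L) %% L
}

# does [start, end) (0-based half-open, possibly wrapping the origin on a
# circular replicon) contain position pos?
interval_contains <- function(start, end, pos, L, circular) {
  if (start <= end) return(pos >= start && pos < end)
  if (!circular) stop("wrapping interval on a linear replicon")
  pos >= start || pos < end
}

# forward-strand slice of a sequence for a 0-based half-open interval,
# wrapping across the origin when start > end on a circular replicon
slice_sequence <- function(sequence, start, end, circular = TRUE) {
  L <- nchar(sequence)
  if (start == end) return("")
  if (start < end) return(substr(sequence, start + 1L, end))
  if (!circular) stop("interval wraps the origin but the replicon is linear")
  paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end))
}

reverse_complement <- function(seq) {
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Promoter identifiers follow the "P + digits" convention: the trailing digit
# run of the gene id (falling back to the locus tag), e.g. a gene id ending in
# 12445 yields P12445.
promoter_id_for <- function(gene_id, locus_tag = NA_character_) {
  src <- gene_id
  digits <- sub(".*?([0-9]+)$", "\\1", src)
  if (identical(digits, src) && !is.na(locus_tag)) {
    src <- locus_tag
    digits <- sub(".*?([0-9]+)$", "\\1", src)
  }
  if (identical(digits, src)) digits <- gsub("[^0-9]", "", src)
  if (!nzchar(digits)) return(paste0("P_", gene_id))
  paste0("P", digits)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
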