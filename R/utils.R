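# Internal helpers shared across modules.

#' @keywords internal
site_key <- function(contig, pos) paste(contig, pos, sep = ":")

# x*log(y) with the 0*log(0) = 0 convention used in binomial log-likelihoods
xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y[nz])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_edscan <- function(fmt, ..., class = "edscan_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Length of the maximal single-nucleotide run containing position `pos`
# (1-based) of sequence string `seq`.
homopolymer_run_length <- function(seq, pos) {
  n <- nchar(seq)
  stopifnot(pos >= 1, pos <= n)
  base <- substr(seq, pos, pos)
  left <- pos
  while (left > 1 && substr(seq, left - 1, left - 1) == base) left <- left - 1
  right <- pos
  while (right < n && substr(seq, right + 1, right + 1) == base) right <- right + 1
  right - left + 1
}

# TRUE where (contig, pos) falls in any interval of `ivs` (1-based closed
# data.frame contig/start/end); vectorized over sites.
in_intervals <- function(contig, pos, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(ivs$contig == contig[i] & ivs$start <= pos[i] & ivs$end >= pos[i])
  }, logical(1))
}

dna_complement <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    dna_complement(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic TSV writer: fixed column order, no quoting surprises.
write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_strict <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop_edscan("file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = colClasses, na.strings = "NA",
                    check.names = FALSE)
}
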