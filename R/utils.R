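# Shared internal helpers: alphabet tables, string utilities, seeded RNG.

.DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> base set, and the inverse (sorted base string -> code).
.IUPAC_MAP <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

.IUPAC_FROM_BASES <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  setNames(
    names(m),
    vapply(strsplit(m, ""), function(b) paste(sort(b), collapse = ""), character(1))
  )
})

.iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC_FROM_BASES[[key]]
  if (is.null(code)) rlang::abort(paste0("no IUPAC code for base set {", key, "}"))
  code
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

.check_dna <- function(seq, arg = "seq", allow_gap = FALSE) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    rlang::abort(paste0("`", arg, "` must be a single non-NA character string"))
  }
  out <- toupper(seq)
  pat <- if (allow_gap) "^[ACGTMRWSYKVHDBN-]*$" else "^[ACGTMRWSYKVHDBN]*$"
  if (!grepl(pat, out)) {
    bad <- unique(setdiff(.chars(out), c(names(.IUPAC_MAP), if (allow_gap) "-")))
    rlang::abort(paste0(
      "`", arg, "` contains non-IUPAC DNA characters: ",
      paste(bad, collapse = ", "), " (note: U/RNA is not accepted)"
    ))
  }
  out
}

# Coerce FASTA tibbles, named character vectors, or bare strings to a named
# character vector of uppercase sequences.
.as_named_seqs <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    out <- setNames(as.character(x$seq), as.character(x$id))
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    rlang::abort(paste0("`", arg, "` must be a FASTA tibble or character vector"))
  }
  vapply(out, .check_dna, character(1), arg = arg)
}

.random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .collapse(sample(.DNA_BASES, n, replace = TRUE, prob = p))
}

# Deterministic per-operation seed stream: mixing the user seed with an
# operation tag keeps generators independent of each other.
.derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L)) + 1L
}

.with_op_seed <- function(seed, op, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(.derive_seed(seed, op), code)
}

.roman <- function(i) as.character(utils::as.roman(i))

.col_or <- function(x, col, default) {
  if (col %in% names(x)) x[[col]] else default
}
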