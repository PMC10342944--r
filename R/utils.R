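# internal helpers

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible child seed (kept well below .Machine$integer.max)
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k * 9973) %% 2147483587L) + 1L
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("'%s' must be TRUE or FALSE", name)
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, format(min), format(max))
  as.numeric(x)
}

# sequences (character vector) -> integer code matrix N x L, codes 1..5,
# anything outside ACGT maps to the N column
seq_to_codes <- function(seqs, width) {
  n <- length(seqs)
  chars <- strsplit(substr(seqs, 1L, width), "", fixed = TRUE)
  codes <- match(unlist(chars, use.names = FALSE), DNA_ALPHABET[1:4])
  codes[is.na(codes)] <- 5L
  matrix(codes, nrow = n, ncol = width, byrow = TRUE)
}

codes_to_seq <- function(codes) {
  m <- matrix(DNA_ALPHABET[codes], nrow = nrow(codes))
  apply(m, 1L, paste0, collapse = "")
}

# one-hot encoding of selected rows over an explicit alphabet size
codes_to_onehot <- function(codes, rows = seq_len(nrow(codes)), nsym = 4L) {
  L <- ncol(codes)
  out <- matrix(0, nrow = length(rows), ncol = L * nsym)
  for (i in seq_along(rows)) {
    sym <- codes[rows[i], ]
    out[i, (seq_len(L) - 1L) * nsym + sym] <- 1
  }
  out
}

random_dna <- function(n, length) {
  m <- matrix(sample(DNA_ALPHABET[1:4], n * length, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}
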