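# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_input(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort_input(sprintf("`%s` = %g is outside its allowed range", name, x))
  if (integerish && abs(x - round(x)) > 1e-8)
    abort_input(sprintf("`%s` = %g must be an integer", name, x))
  invisible(x)
}

# Row-wise Pearson correlation between two matrices of equal shape.
# Rows with zero variance on either side yield NA.
row_pearson <- function(x, y) {
  x <- x - rowMeans(x)
  y <- y - rowMeans(y)
  sx <- sqrt(rowSums(x * x))
  sy <- sqrt(rowSums(y * y))
  num <- rowSums(x * y)
  out <- num / (sx * sy)
  out[sx == 0 | sy == 0] <- NA_real_
  out
}

# Numerically stable log(sum(exp(x))) per row.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# Largest-remainder apportionment of n items over fractions summing to 1.
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# md5 of an arbitrary R object via serialization (model fingerprints,
# pipeline cache keys).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
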