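# internal helpers

# run expr with a local RNG state seeded at `seed`; global stream untouched
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 12 significant digits, locale-independent
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) ifelse(v > 0, "Inf", "-Inf")
    else sprintf("%.12g", v)
  }, character(1L))
  out
}

writeTsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmtNum)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
}

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
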