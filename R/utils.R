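#' @import data.table
#' @importFrom stats coef lm median model.matrix p.adjust pt quantile rbinom
#'   rnbinom rnorm rpois runif sd setNames var rmultinom cor complete.cases
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child-seed derivation so pipeline stages can be rerun in
# isolation; keeps results inside the 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647L)
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

# Unordered gene-pair key: "A|B" with lexicographic ordering.
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
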