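stopf <- function(fmt, ..., class = "sconet_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition"),
                      call = sys.call(-1)))
}

#' @noRd
msg <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a reproducible child seed from a master seed and a string tag, so
# that e.g. adding a clinical score does not perturb the morphometry draws.
split_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Truncated-at-lower-bound Gaussian draw by rejection (vectorized).
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    guard <- guard + 1L
  }
  x[x < lower] <- lower
  x
}

# Cheap deterministic content hash for provenance lines in output files.
content_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  codes <- utf8ToInt(s)
  h1 <- 5381; h2 <- 52711
  for (k in codes) {
    h1 <- (h1 * 33 + k) %% 2147483629
    h2 <- (h2 * 31 + k) %% 2147483587
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}
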