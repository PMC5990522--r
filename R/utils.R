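# internal helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype token <-> integer code (1 present, 0 absent, NA missing)
GT_TOKENS <- c(absent = 0L, present = 1L)

gt_to_token <- function(x) {
  out <- rep("missing", length(x))
  out[!is.na(x) & x == 1L] <- "present"
  out[!is.na(x) & x == 0L] <- "absent"
  out
}

token_to_gt <- function(x) {
  bad <- setdiff(unique(x), c("present", "absent", "missing"))
  if (length(bad) > 0)
    stop_fmt("unknown genotype token(s): %s", paste(bad, collapse = ", "))
  out <- rep(NA_integer_, length(x))
  out[x == "present"] <- 1L
  out[x == "absent"] <- 0L
  out
}
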