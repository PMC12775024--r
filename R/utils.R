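# Internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1) # x first: keeps dim attributes

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

# Seeded evaluation with full RNG-kind pinning, restoring the caller's state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Derived sub-seed, kept inside 32-bit signed range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 7919 + as.double(salt)) %% 2147483647)
}

# Row-wise numerically stable softmax on a matrix of logits.
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# argmax with lowest-index tie-break, returned as 0-based class label.
argmax_label <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  max.col(logits, ties.method = "first") - 1L
}

# Mean cross-entropy of integer labels (0-based) under raw logits, via
# log-sum-exp; returns the loss and the gradient wrt logits.
cross_entropy <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  picked <- logits[cbind(seq_len(n), labels + 1L)]
  p <- softmax(logits)
  grad <- p
  grad[cbind(seq_len(n), labels + 1L)] <- grad[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = mean(lse - picked), grad = grad / n, prob = p)
}

# Run-length encoding of a logical mask (column-major vector order),
# JSON-friendly: alternating run lengths starting with a run of FALSE.
rle_encode_mask <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  v <- as.logical(mask)
  if (!length(v)) return(list(dims = dim(mask), runs = integer(0)))
  r <- rle(v)
  runs <- r$lengths
  if (r$values[1L]) runs <- c(0L, runs) # canonical: first run counts FALSE
  list(dims = as.integer(dim(mask)), runs = as.integer(runs))
}

rle_decode_mask <- function(enc) {
  dims <- as.integer(enc$dims)
  runs <- as.integer(enc$runs)
  n <- prod(dims)
  if (!length(runs)) return(array(FALSE, dims))
  vals <- rep(c(FALSE, TRUE), length.out = length(runs))
  v <- rep(vals, runs)
  stopifnot(length(v) == n)
  array(v, dims)
}

# Stack a list of equally shaped (C,H,W) arrays into a (C,H,W,N) batch.
stack_chw <- function(lst) {
  d <- dim(lst[[1L]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}
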