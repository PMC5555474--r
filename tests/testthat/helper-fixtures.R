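# shared fixtures: a scaled-down 45S unit keeps alignment work small while
# preserving the subunit structure the analyses assume

small_unit <- function(seed = 11L) {
  generate_reference_unit(
    subunit_lengths = c("18S" = 300L, "ITS1" = 60L, "5.8S" = 100L,
                        "ITS2" = 60L, "28S" = 500L, "IGS" = 200L),
    subunit_gc = c("18S" = 0.48, "ITS1" = 0.50, "5.8S" = 0.48,
                   "ITS2" = 0.50, "28S" = 0.48, "IGS" = 0.50),
    seed = seed
  )
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a fraction of positions to a random different base
mutate_frac <- function(seq, frac, seed) {
  set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), round(frac * length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

uniform_rip <- function(rate, background = 0, seed = 1L) {
  rip_params(context_rates = c(CpA = rate, CpC = rate, CpG = rate,
                               CpT = rate),
             background_rate = background, seed = seed)
}

# independent affine-gap alignment score oracle: plain three-matrix
# dynamic program in R, no traceback, no shared code with the package
oracle_affine_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 5, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
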