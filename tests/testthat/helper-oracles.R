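# Independent oracles: deliberately plain re-implementations used only to
# check the package's optimised code paths.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y")

random_protein_str <- function(n) {
  paste0("M", paste(sample(AA_LETTERS, n - 1, replace = TRUE), collapse = ""))
}

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_cds <- function(n_codons) {
  paste0(paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
               collapse = ""), "TAA")
}

# --- global alignment oracle: textbook Gotoh DP in plain R ----------------
# Same conventions as the implementation contract: BLOSUM62, gap of length
# L costs open + ext * L, traceback prefers match state, then gap-in-b
# (vertical), then gap-in-a.
oracle_nw <- function(a, b, gap_open = 11, gap_ext = 1) {
  sub <- local({
    e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) { X[i + 1, 1] <- -(gap_open + gap_ext * i); tX[i + 1, 1] <- 1L }
  for (j in seq_len(m)) { Y[1, j + 1] <- -(gap_open + gap_ext * j); tY[1, j + 1] <- 2L }
  argmax3 <- function(v) {  # prefer M, then X, then Y on ties
    w <- which(v == max(v)); w[1]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- c(M[i, j], X[i, j], Y[i, j])
      k <- argmax3(d)
      M[i + 1, j + 1] <- d[k] + sub[A[i], B[j]]
      tM[i + 1, j + 1] <- k - 1L
      u <- c(M[i, j + 1] - (gap_open + gap_ext),
             X[i, j + 1] - gap_ext,
             Y[i, j + 1] - (gap_open + gap_ext))
      k <- argmax3(u)
      X[i + 1, j + 1] <- u[k]; tX[i + 1, j + 1] <- k - 1L
      l <- c(M[i + 1, j] - (gap_open + gap_ext),
             X[i + 1, j] - (gap_open + gap_ext),
             Y[i + 1, j] - gap_ext)
      k <- argmax3(l)
      Y[i + 1, j + 1] <- l[k]; tY[i + 1, j + 1] <- k - 1L
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- argmax3(fin) - 1L
  score <- fin[state + 1L]
  i <- n; j <- m; ncols <- 0L; nmatch <- 0L
  while (i > 0 || j > 0) {
    if (state == 0L) {
      ncols <- ncols + 1L
      if (A[i] == B[j]) nmatch <- nmatch + 1L
      state <- tM[i + 1, j + 1]; i <- i - 1L; j <- j - 1L
    } else if (state == 1L) {
      ncols <- ncols + 1L
      state <- tX[i + 1, j + 1]; i <- i - 1L
    } else {
      ncols <- ncols + 1L
      state <- tY[i + 1, j + 1]; j <- j - 1L
    }
  }
  list(score = score, identity = 100 * nmatch / ncols)
}

# --- ENC oracle: step-by-step Wright computation --------------------------
oracle_enc <- function(cds) {
  fams <- list(
    F = c("TTT", "TTC"), Y = c("TAT", "TAC"), C = c("TGT", "TGC"),
    H = c("CAT", "CAC"), Q = c("CAA", "CAG"), N = c("AAT", "AAC"),
    K = c("AAA", "AAG"), D = c("GAT", "GAC"), E = c("GAA", "GAG"),
    I = c("ATT", "ATC", "ATA"),
    V = c("GTT", "GTC", "GTA", "GTG"), P = c("CCT", "CCC", "CCA", "CCG"),
    T = c("ACT", "ACC", "ACA", "ACG"), A = c("GCT", "GCC", "GCA", "GCG"),
    G = c("GGT", "GGC", "GGA", "GGG"),
    L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  if (codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    codons <- codons[-length(codons)]
  fhat <- sapply(fams, function(cc) {
    cnt <- sapply(cc, function(c1) sum(codons == c1))
    ntot <- sum(cnt)
    if (ntot < 2) return(NA_real_)
    f <- (ntot * sum((cnt / ntot)^2) - 1) / (ntot - 1)
    if (f <= 0) NA_real_ else f
  })
  sizes <- lengths(fams)
  cls_mean <- function(k) {
    v <- fhat[sizes == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  f2 <- cls_mean(2); f3 <- cls_mean(3); f4 <- cls_mean(4); f6 <- cls_mean(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (any(is.na(c(f2, f3, f4, f6)))) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# --- competitive assignment oracle: per-read brute-force scan -------------
oracle_competitive <- function(hits) {
  out <- character(0)
  for (r in unique(hits$read_id)) {
    h <- hits[hits$read_id == r, ]
    h <- h[h$identity == max(h$identity), ]
    h <- h[h$score == max(h$score), ]
    out[r] <- min(h$genome_id)
  }
  out
}

# --- agglomerative clustering oracle: complete linkage, brute force -------
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- small simulated clade shared across tests ----------------------------
small_clade <- function(seed = 11, ...) {
  args <- list(n_focal = 2, n_background = 2, n_core_genes = 40,
               gene_length_codons = c(60L, 120L), ani_targets = 0.05,
               unique_genes_per_focal = 6, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_clade(do.call(clade_config, args))
}
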