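# Independent brute-force oracles, written from the definitions and kept
# deliberately naive: they share no code with the package implementations.

# -- parsimony-informative sites: per-column table() scan ---------------------
brute_pis <- function(aln) {
  m <- aln$matrix
  sites <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) next
    tab <- table(col)
    if (sum(tab >= 2) >= 2) sites <- c(sites, j - 1L)
  }
  sites
}

# -- indel events: explicit per-character run scan ----------------------------
brute_indels <- function(aln, include_terminal = FALSE) {
  m <- aln$matrix
  ev <- list()
  for (tx in rownames(m)) {
    row <- m[tx, ]
    j <- 1
    while (j <= length(row)) {
      if (row[j] == "-") {
        start <- j
        while (j <= length(row) && row[j] == "-") j <- j + 1
        end <- j - 1
        terminal <- start == 1 || end == length(row)
        if (include_terminal || !terminal) {
          key <- paste(start - 1, end, sep = ":")  # 0-based half-open
          ev[[key]] <- c(ev[[key]], tx)
        }
      } else j <- j + 1
    }
  }
  if (length(ev) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      carriers = character()))
  }
  se <- do.call(rbind, strsplit(names(ev), ":"))
  out <- data.frame(start = as.integer(se[, 1]), end = as.integer(se[, 2]))
  out$carriers <- vapply(ev, function(x) paste(sort(x), collapse = ","),
                         character(1))
  out[order(out$start, out$end), ]
}

# -- SSR arrays: per-start forward extension with substring comparison --------
brute_ssr <- function(s, thresholds = ssr_thresholds()) {
  s <- toupper(s)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  is_base <- function(i) chars[i] %in% c("A", "C", "G", "T")
  canon <- function(mot) {
    k <- nchar(mot)
    if (k == 1) return(mot)
    min(vapply(1:k, function(i) paste0(substr(mot, i, k),
                                       substr(mot, 1, i - 1)), ""))
  }
  primitive <- function(mot) {
    k <- nchar(mot)
    if (k == 1) return(TRUE)
    !any(vapply(1:(k - 1), function(p)
      k %% p == 0 && strrep(substr(mot, 1, p), k / p) == mot, logical(1)))
  }
  hits <- list()
  for (m in 1:6) {
    min_rep <- thresholds[[as.character(m)]]
    i <- 1
    while (i + 2 * m - 1 <= n) {
      motif <- substr(s, i, i + m - 1)
      left_max <- i == 1 || !is_base(i - 1) ||
        chars[i - 1] != chars[i - 1 + m]
      if (left_max && all(vapply(i:(i + m - 1), is_base, logical(1)))) {
        reps <- 1
        while (i + (reps + 1) * m - 1 <= n &&
               substr(s, i + reps * m, i + (reps + 1) * m - 1) == motif &&
               all(vapply((i + reps * m):(i + (reps + 1) * m - 1), is_base,
                          logical(1)))) {
          reps <- reps + 1
        }
        if (reps >= min_rep && primitive(motif)) {
          hits[[length(hits) + 1]] <- data.frame(
            motif = canon(motif), repeats = reps, start = i - 1L,
            end = i - 1L + reps * m, length = reps * m)
        }
      }
      i <- i + 1
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif = character(), repeats = integer(),
                      start = integer(), end = integer(),
                      length = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$length, out$start, nchar(out$motif)), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (out$start[j] < out$end[i] && out$end[j] > out$start[i]) {
        keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, ]
  out[order(out$start), ]
}

# -- global affine-gap alignment: full three-state DP -------------------------
# gap of length k costs open + k * extend (both positive numbers here)
nw_affine_score <- function(a, b, match = 1, mismatch = -1, open = 4,
                            extend = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consume x)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consume y)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * extend
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score an existing pairwise alignment under the same affine scheme
score_pairwise <- function(a, b, match = 1, mismatch = -1, open = 4,
                           extend = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  sc <- 0
  in_gap_x <- FALSE; in_gap_y <- FALSE
  for (i in seq_along(x)) {
    if (x[i] == "-" && y[i] == "-") next
    if (x[i] == "-") {
      sc <- sc - extend - if (in_gap_x) 0 else open
      in_gap_x <- TRUE; in_gap_y <- FALSE
    } else if (y[i] == "-") {
      sc <- sc - extend - if (in_gap_y) 0 else open
      in_gap_y <- TRUE; in_gap_x <- FALSE
    } else {
      sc <- sc + if (x[i] == y[i]) match else mismatch
      in_gap_x <- FALSE; in_gap_y <- FALSE
    }
  }
  sc
}
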