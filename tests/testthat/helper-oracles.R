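# Independent brute-force oracles used to cross-check the implementation.

# flood-fill connected components (BFS over an explicit queue)
floodFillLabels <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    offs <- expand.grid(dr = -1:1, dc = -1:1)
    offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  } else {
    offs <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        ri <- p[1] + offs$dr[k]; cj <- p[2] + offs$dc[k]
        if (ri >= 1 && ri <= nr && cj >= 1 && cj <= nc &&
            mask[ri, cj] && lab[ri, cj] == 0L) {
          lab[ri, cj] <- cur
          queue[[length(queue) + 1]] <- c(ri, cj)
        }
      }
    }
  }
  lab
}

# two labelings agree iff they induce the same pixel partition
samePartition <- function(labA, labB) {
  fa <- labA[labA > 0 | labB > 0]
  fb <- labB[labA > 0 | labB > 0]
  if (any(fa == 0) || any(fb == 0)) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}

# exhaustive Otsu: try every split point of the binned histogram and score
# between-class variance directly from the raw values
bruteForceOtsu <- function(x, levels = 256L) {
  r <- range(x)
  w <- (r[2] - r[1]) / levels
  edges <- r[1] + seq_len(levels - 1L) * w
  best <- -Inf; bestEdge <- edges[1]
  for (e in edges) {
    lo <- x[x <= e]; hi <- x[x > e]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    score <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (score > best) { best <- score; bestEdge <- e }
  }
  bestEdge
}
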