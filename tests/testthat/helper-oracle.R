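# Exhaustive flood-fill connected-component labeling on a 2D logical matrix.
# Deliberately naive (explicit stack, pixel-at-a-time) so it is independent of
# the union-find implementation under test.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- as.matrix(expand.grid(-1:1, -1:1))
    nb <- nb[rowSums(abs(nb)) > 0, ]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition if the label-pair mapping is a
# bijection on foreground pixels.
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  f <- a > 0
  pairs <- unique(cbind(a[f], b[f]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# Analytic dead+dying volume for a sphere of radius R consumed by an inward
# front at depth d (um): the shell between R and max(R - d, 0).
shell_volume <- function(R, d) {
  inner <- max(R - d, 0)
  4 / 3 * pi * (R^3 - inner^3)
}
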