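# Interval utilities used by the artifact mask and segment bookkeeping.
# All intervals are half-open [start, end) in seconds, as two-column matrices.

merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- list()
  cur <- iv[1L, ]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], iv[i, 2L])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- iv[i, ]
    }
  }
  out[[length(out) + 1L]] <- cur
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

clip_intervals <- function(iv, lo, hi) {
  if (nrow(iv) == 0L) return(iv)
  iv[, 1L] <- pmax(iv[, 1L], lo)
  iv[, 2L] <- pmin(iv[, 2L], hi)
  iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
}

# complement of a merged interval set within [lo, hi)
complement_intervals <- function(iv, lo, hi) {
  if (nrow(iv) == 0L)
    return(matrix(c(lo, hi), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  iv <- merge_intervals(clip_intervals(iv, lo, hi))
  starts <- c(lo, iv[, 2L])
  ends <- c(iv[, 1L], hi)
  keep <- ends > starts
  m <- cbind(start = starts[keep], end = ends[keep])
  m
}

interval_total <- function(iv) if (nrow(iv) == 0L) 0 else sum(iv[, 2L] - iv[, 1L])

# total length of the overlap between [a0, a1) and an interval set
overlap_with_set <- function(a0, a1, iv) {
  if (nrow(iv) == 0L) return(0)
  lo <- pmax(iv[, 1L], a0)
  hi <- pmin(iv[, 2L], a1)
  sum(pmax(hi - lo, 0))
}

# assumes iv merged and sorted; [start, end) membership via boundary parity
point_in_set <- function(x, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(x)))
  findInterval(x, as.vector(t(iv))) %% 2L == 1L
}
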