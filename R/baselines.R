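#' Victor-Purpura spike train distance
#'
#' Edit distance between two spike trains with insertion/deletion cost 1 and
#' shift cost \code{q} per unit time (capped at 2 by deleting and
#' re-inserting), computed by the standard dynamic program.  At \code{q = 0}
#' it equals the absolute difference in spike counts; as \code{q} grows it
#' converges to the sum of the two counts.  For equal-count trains contained
#' in a window of length \code{T}, \code{(T/n) * victorPurpura(a, b, 1/T)}
#' equals the absolute-time earth mover distance \code{\link{emdAbsolute}}.
#'
#' @param a,b numeric spike-time vectors; empty trains are legal
#'   (\code{victorPurpura(numeric(0), b, q)} is \code{length(b)}, pure
#'   insertions).
#' @param q non-negative shift cost per unit time.
#' @return non-negative scalar distance.
#' @examples
#' victorPurpura(c(1, 2, 3), 5, q = 0)    # |3 - 1| = 2
#' victorPurpura(c(1, 2, 3), 5, q = 1e6)  # 3 + 1 = 4
#' @export
victorPurpura <- function(a, b, q) {
  if (length(q) != 1 || !is.finite(q) || q < 0)
    stop("victorPurpura: q must be a non-negative number")
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(na + nb)
  prev <- 0:nb
  cur <- numeric(nb + 1)
  for (i in seq_len(na)) {
    cur[1] <- i
    shift <- pmin(q * abs(a[i] - b), 2)
    for (j in seq_len(nb))
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + shift[j])
    prev <- cur
  }
  prev[nb + 1]
}

#' Per-neuron-averaged Victor-Purpura matrix
#'
#' Multi-neuron Victor-Purpura dissimilarity between all epoch pairs,
#' computed per neuron and averaged over neurons — the variant of the
#' multi-neuron extension with label-exchange cost at or above the
#' insert-delete cap, where spikes never swap neuron identities.
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} object.
#' @param q non-negative shift cost per unit time.
#' @return symmetric M x M matrix with epoch ids as dimnames.
#' @export
vpMatrix <- function(x, q) {
  stopifnot(is(x, "EpochedSpikes"))
  M <- nEpochs(x); N <- nNeurons(x)
  if (M < 2) stop("vpMatrix: need >=2 epochs")
  D <- matrix(0, M, M, dimnames = list(x@epochIds, x@epochIds))
  for (k in seq_len(M - 1)) for (m in (k + 1):M) {
    d <- mean(vapply(seq_len(N), function(i)
      victorPurpura(x@trains[[k]][[i]], x@trains[[m]][[i]], q), numeric(1)))
    D[k, m] <- D[m, k] <- d
  }
  D
}

#' Per-epoch firing rate vectors
#'
#' Spike count of each neuron in each epoch divided by the window length.
#'
#' @param x an \code{\linkS4class{EpochedSpikes}} object.
#' @param T epoch window length (same time unit as the spikes), positive.
#' @return N x M matrix of rates (neurons x epochs).
#' @export
rateVectors <- function(x, T) {
  stopifnot(is(x, "EpochedSpikes"))
  if (length(T) != 1 || !is.finite(T) || T <= 0)
    stop("rateVectors: T must be a positive number")
  counts <- vapply(x@trains, lengths, integer(nNeurons(x)))
  counts <- matrix(counts, nrow = nNeurons(x),
                   dimnames = list(x@neuronIds, x@epochIds))
  counts / T
}

#' Euclidean distance between z-scored firing rate vectors
#'
#' Per neuron, firing rates are z-scored across epochs using the population
#' (divide-by-M) standard deviation; neurons with zero rate variance across
#' epochs get z-score 0 everywhere, so constant neurons drop out of the
#' distance.  The result is the pairwise Euclidean distance between the
#' z-scored epoch rate vectors — the conventional rate-code companion to the
#' timing-based dissimilarity.
#'
#' @inheritParams rateVectors
#' @return symmetric M x M matrix with epoch ids as dimnames.
#' @examples
#' # two epochs with rate vectors (3,4,5) and (2,5,3) z-score to
#' # (1,-1,1) and (-1,1,-1); their distance is sqrt(12)
#' @export
rateDistanceMatrix <- function(x, T) {
  R <- rateVectors(x, T)            # N x M
  M <- ncol(R)
  if (M < 2) stop("rateDistanceMatrix: need >=2 epochs")
  mu <- rowMeans(R)
  sdev <- sqrt(rowMeans((R - mu)^2))  # population convention
  Z <- (R - mu) / ifelse(sdev > 0, sdev, 1)
  Z[sdev == 0, ] <- 0
  D <- as.matrix(stats::dist(t(Z)))
  dimnames(D) <- list(colnames(R), colnames(R))
  D
}

#' Discriminability index on a dissimilarity matrix
#'
#' For each label, compares the off-diagonal distances within that label
#' (both epochs share it) against the distances between the label and all
#' other epochs (exactly one member has it):
#' \deqn{d = (\mu_{between} - \mu_{within}) / \sqrt{s^2_{between} + s^2_{within}}}
#' a d-prime-style separation in pooled standard-deviation units.  Variances
#' use the population (divide-by-count) convention so a label with a single
#' within pair is still defined.  A zero denominator with a positive
#' numerator is reported as \code{Inf} (perfect separation) and flagged.
#'
#' @param D symmetric M x M dissimilarity matrix.
#' @param labels vector of M epoch labels.
#' @return data.frame with one row per label: \code{label}, \code{n_epochs},
#'   \code{mu_within}, \code{mu_between}, \code{s2_within},
#'   \code{s2_between}, \code{d}, \code{flagged} (TRUE when \code{d} is not
#'   a finite ratio: singleton label or degenerate variances).
#' @export
discriminabilityIndex <- function(D, labels) {
  D <- as.matrix(D)
  M <- nrow(D)
  if (ncol(D) != M || length(labels) != M)
    stop("discriminabilityIndex: labels must cover all epochs of a square D")
  labels <- as.character(labels)
  popvar <- function(v) mean((v - mean(v))^2)
  out <- lapply(unique(labels), function(lb) {
    idx <- which(labels == lb)
    if (length(idx) < 2)
      return(data.frame(label = lb, n_epochs = length(idx),
                        mu_within = NA_real_, mu_between = NA_real_,
                        s2_within = NA_real_, s2_between = NA_real_,
                        d = NA_real_, flagged = TRUE))
    win <- D[idx, idx][upper.tri(diag(length(idx)))]
    bet <- as.vector(D[idx, -idx, drop = FALSE])
    if (length(bet) == 0)   # label covers every epoch: no between pairs
      return(data.frame(label = lb, n_epochs = length(idx),
                        mu_within = mean(win), mu_between = NA_real_,
                        s2_within = popvar(win), s2_between = NA_real_,
                        d = NA_real_, flagged = TRUE))
    s2w <- popvar(win); s2b <- popvar(bet)
    den <- sqrt(s2b + s2w)
    num <- mean(bet) - mean(win)
    d <- if (den > 0) num / den else if (num != 0) Inf * sign(num) else NaN
    data.frame(label = lb, n_epochs = length(idx),
               mu_within = mean(win), mu_between = mean(bet),
               s2_within = s2w, s2_between = s2b, d = d,
               flagged = !is.finite(d))
  })
  do.call(rbind, out)
}
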