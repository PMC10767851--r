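#' RegSeq: a small multitask open-chromatin CNN
#'
#' A compact convolutional network over 500 bp of one-hot DNA predicting,
#' per cell type, the probability that the sequence sits in open chromatin,
#' plus one head trained on GC-matched background sequences. Architecture
#' (configurable): three valid convolutions with ReLU and max-pooling,
#' one dense ReLU layer, and a sigmoid output head per task. The network
#' is implemented directly in base R matrix algebra (im2col convolutions,
#' Adam optimizer) so it trains in seconds at desk scale and is exactly
#' reproducible for a given seed.
#'
#' @name regseq
NULL

#' RegSeq architecture configuration
#'
#' @param input_len Input window length in bp.
#' @param conv_filters,kernel,pool Per-conv-layer filter counts, kernel
#'   widths and max-pool sizes.
#' @param dense Width of the dense hidden layer.
#' @return A list of architecture hyperparameters.
#' @export
regseq_config <- function(input_len = 500L, conv_filters = c(64L, 64L, 32L),
                          kernel = c(8L, 8L, 8L), pool = c(4L, 4L, 4L),
                          dense = 64L) {
  list(input_len = as.integer(input_len),
       conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
       pool = as.integer(pool), dense = as.integer(dense))
}

#' One-hot encode DNA sequences
#'
#' @param seqs Character vector of equal-length DNA sequences; `N` (or any
#'   non-ACGT base) encodes as an all-zero channel vector.
#' @return An array `n x L x 4` (channels A, C, G, T).
#' @export
one_hot_dna <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1) abort("sequences must share one length")
  X <- array(0, c(n, L, 4))
  chars <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = n, byrow = TRUE)
  for (b in 1:4) {
    X[, , b][chars == BASES[b]] <- 1
  }
  X
}

# ---- low-level net ---------------------------------------------------------
# leaky rectifier (slope 0.1 below zero) keeps units trainable: with plain
# ReLU the first conv layer can die wholesale early in training
LRELU_ALPHA <- 0.1
lrelu <- function(z) z * ((z > 0) + LRELU_ALPHA * (z <= 0))
lrelu_grad <- function(z) (z > 0) + LRELU_ALPHA * (z <= 0)
# Activations are held as flat matrices of dim (n * L) x C with row index
# r = i + (l - 1) * n; this keeps every conv / pool step a plain matrix
# operation on contiguous memory.

# row indices of input position (l + off) for every output position l
shift_idx <- function(n, Lout, off, stride = 1L) {
  as.vector(outer(seq_len(n), (seq.int(0L, Lout - 1L) * stride + off) * n, `+`))
}

im2col <- function(Xm, n, L, Cin, k) {
  Lout <- L - k + 1L
  out <- matrix(0, n * Lout, k * Cin)
  for (j in seq_len(k)) {
    out[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Xm[shift_idx(n, Lout, j - 1L), ]
  }
  out
}

col2im <- function(dXc, n, L, Cin, k) {
  Lout <- L - k + 1L
  dX <- matrix(0, n * L, Cin)
  for (j in seq_len(k)) {
    idx <- shift_idx(n, Lout, j - 1L)
    dX[idx, ] <- dX[idx, ] + dXc[, ((j - 1L) * Cin + 1L):(j * Cin)]
  }
  dX
}

maxpool_fwd <- function(R, n, L, p) {
  Lp <- L %/% p
  idx1 <- shift_idx(n, Lp, 0L, stride = p)
  M <- R[idx1, , drop = FALSE]
  J <- matrix(1L, nrow(M), ncol(M))
  if (p > 1) {
    for (j in 2:p) {
      Rj <- R[shift_idx(n, Lp, j - 1L, stride = p), , drop = FALSE]
      upd <- Rj > M
      M[upd] <- Rj[upd]
      J[upd] <- j
    }
  }
  list(out = M, argmax = J, in_len = L, out_len = Lp)
}

maxpool_bwd <- function(dM, cache, n, C, p) {
  dR <- matrix(0, n * cache$in_len, C)
  for (j in seq_len(p)) {
    sel <- cache$argmax == j
    if (!any(sel)) next
    idx <- shift_idx(n, cache$out_len, j - 1L, stride = p)
    blk <- dR[idx, , drop = FALSE]
    blk[sel] <- dM[sel]
    dR[idx, ] <- blk
  }
  dR
}

init_weights <- function(arch, seed) {
  withr::with_seed(seed, {
    W <- list(); Cin <- 4L
    for (l in seq_along(arch$conv_filters)) {
      fanin <- arch$kernel[l] * Cin
      W[[paste0("Wc", l)]] <- matrix(rnorm(fanin * arch$conv_filters[l],
                                           sd = sqrt(2 / fanin)),
                                     fanin, arch$conv_filters[l])
      W[[paste0("bc", l)]] <- numeric(arch$conv_filters[l])
      Cin <- arch$conv_filters[l]
    }
    Lf <- flat_len(arch)
    W$Wd <- matrix(rnorm(Lf * arch$dense, sd = sqrt(2 / Lf)), Lf, arch$dense)
    W$bd <- numeric(arch$dense)
    W$Wh <- NULL  # head weights added once the head count is known
    W
  })
}

flat_len <- function(arch) {
  L <- arch$input_len
  for (l in seq_along(arch$conv_filters)) {
    L <- (L - arch$kernel[l] + 1L) %/% arch$pool[l]
  }
  L * arch$conv_filters[length(arch$conv_filters)]
}

net_forward <- function(W, X, arch, keep_cache = FALSE, dropout = NULL) {
  n <- dim(X)[1]
  A <- matrix(X, n * dim(X)[2], dim(X)[3])  # (n*L) x 4, row = i + (l-1)*n
  L <- dim(X)[2]; Cin <- dim(X)[3]
  cache <- list(n = n)
  for (l in seq_along(arch$conv_filters)) {
    k <- arch$kernel[l]
    Xc <- im2col(A, n, L, Cin, k)
    Z <- Xc %*% W[[paste0("Wc", l)]]
    Z <- Z + rep(W[[paste0("bc", l)]], each = nrow(Z))
    R <- lrelu(Z)
    mp <- maxpool_fwd(R, n, L - k + 1L, arch$pool[l])
    if (keep_cache) {
      cache[[paste0("Xc", l)]] <- Xc
      cache[[paste0("Z", l)]] <- Z
      cache[[paste0("mp", l)]] <- mp
      cache[[paste0("inlen", l)]] <- L
      cache[[paste0("inC", l)]] <- Cin
    }
    A <- mp$out
    L <- mp$out_len
    Cin <- ncol(A)
  }
  Fl <- matrix(A, n, L * Cin)
  if (!is.null(dropout)) Fl <- Fl * dropout$mF
  Zd <- sweep(Fl %*% W$Wd, 2, W$bd, "+")
  H <- lrelu(Zd)
  if (!is.null(dropout)) H <- H * dropout$mH
  logits <- sweep(H %*% W$Wh, 2, W$bh, "+")
  probs <- 1 / (1 + exp(-logits))
  if (keep_cache) {
    cache$Fl <- Fl; cache$Zd <- Zd; cache$H <- H
    cache$final_len <- L; cache$final_C <- Cin
    cache$dropout <- dropout
    list(probs = probs, cache = cache)
  } else probs
}

net_backward <- function(W, Y, probs, cache, arch) {
  n <- cache$n
  g <- list()
  dlog <- (probs - Y) / (n * ncol(Y))
  g$Wh <- crossprod(cache$H, dlog)
  g$bh <- colSums(dlog)
  dH <- dlog %*% t(W$Wh)
  if (!is.null(cache$dropout)) dH <- dH * cache$dropout$mH
  dZd <- dH * lrelu_grad(cache$Zd)
  g$Wd <- crossprod(cache$Fl, dZd)
  g$bd <- colSums(dZd)
  dFl <- dZd %*% t(W$Wd)
  if (!is.null(cache$dropout)) dFl <- dFl * cache$dropout$mF
  dA <- matrix(dFl, n * cache$final_len, cache$final_C)
  for (l in rev(seq_along(arch$conv_filters))) {
    k <- arch$kernel[l]
    Lin <- cache[[paste0("inlen", l)]]
    dR <- maxpool_bwd(dA, cache[[paste0("mp", l)]], n,
                      arch$conv_filters[l], arch$pool[l])
    dZ <- dR * lrelu_grad(cache[[paste0("Z", l)]])
    g[[paste0("Wc", l)]] <- crossprod(cache[[paste0("Xc", l)]], dZ)
    g[[paste0("bc", l)]] <- colSums(dZ)
    if (l > 1) {
      dXc <- dZ %*% t(W[[paste0("Wc", l)]])
      dA <- col2im(dXc, n, Lin, cache[[paste0("inC", l)]], k)
    }
  }
  g
}

adam_step <- function(W, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (nm in names(g)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g[[nm]] * 0
      state$v[[nm]] <- g[[nm]] * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !startsWith(nm, "b")) {
      W[[nm]] <- W[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(W = W, state = state)
}

# chunked inference keeps the im2col working set small
net_predict <- function(W, X, arch, chunk = 64L) {
  n <- dim(X)[1]
  out <- NULL
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    out <- rbind(out, net_forward(W, X[s, , , drop = FALSE], arch))
  }
  out
}

bce_loss <- function(probs, Y) {
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -mean(Y * log(p) + (1 - Y) * log(1 - p))
}

# ---- user-facing ops -------------------------------------------------------

#' Sample GC-matched background intervals
#'
#' Draws one negative interval per positive, uniformly from regions not
#' overlapping any positive, requiring the negative's GC fraction to fall
#' in the same 5%-wide GC bin as its matched positive. After `max_retry`
#' failed draws for a positive the nearest available GC bin is accepted
#' (with a warning).
#'
#' @param positives A tibble `contig`, `start`, `end` (1-based inclusive).
#' @param reference Named character vector or `DNAStringSet`.
#' @param seed Integer seed.
#' @param bin_width GC bin width (default 0.05).
#' @param max_retry Draws attempted per positive before the nearest-bin
#'   fallback.
#' @return A tibble `contig`, `start`, `end`, `gc`, one row per positive.
#' @export
sample_gc_matched_negatives <- function(positives, reference, seed = 1L,
                                        bin_width = 0.05, max_retry = 200L) {
  reference <- as_reference(reference)
  if (nrow(positives) == 0) abort("positives is empty")
  withr::local_seed(seed)
  gc_of <- function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }
  pos_gc <- mapply(function(c, s, e) gc_of(ref_slice(reference, c, s, e)),
                   positives$contig, positives$start, positives$end)
  binno <- function(gc) floor(gc / bin_width)
  # free space: per contig, positions whose window does not overlap positives
  ctgs <- names(reference)
  free <- lapply(ctgs, function(ctg) {
    n <- nchar(reference[[ctg]])
    occ <- rep(FALSE, n)
    p <- positives[positives$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(p))) occ[p$start[i]:p$end[i]] <- TRUE
    occ
  })
  names(free) <- ctgs
  total_free <- sum(vapply(free, function(o) sum(!o), 0))
  if (total_free < max(positives$end - positives$start + 1)) {
    abort("reference exhausted: no negative space left")
  }
  fallback <- 0L
  out <- vector("list", nrow(positives))
  for (i in seq_len(nrow(positives))) {
    w <- positives$end[i] - positives$start[i] + 1L
    want <- binno(pos_gc[i])
    got <- NULL; best <- NULL; best_gap <- Inf
    for (try in seq_len(max_retry)) {
      ctg <- sample(ctgs, 1L)
      n <- nchar(reference[[ctg]])
      if (n < w) next
      s <- sample.int(n - w + 1L, 1L)
      if (any(free[[ctg]][s:(s + w - 1L)])) next
      gc <- gc_of(ref_slice(reference, ctg, s, s + w - 1L))
      gap <- abs(binno(gc) - want)
      if (gap == 0) {
        got <- tibble(contig = ctg, start = s, end = s + w - 1L, gc = gc)
        break
      }
      if (gap < best_gap) {
        best_gap <- gap
        best <- tibble(contig = ctg, start = s, end = s + w - 1L, gc = gc)
      }
    }
    if (is.null(got)) {
      if (is.null(best)) abort("reference exhausted while sampling negatives")
      got <- best
      fallback <- fallback + 1L
    }
    out[[i]] <- got
  }
  if (fallback > 0) {
    warn(paste0(fallback, " negative(s) fell back to the nearest GC bin"))
  }
  bind_rows(out)
}

#' Train the RegSeq model
#'
#' Multitask binary cross-entropy over one head per cell type plus a
#' background head that is positive on the GC-matched negatives. 20% of
#' the data are held out for per-head AUROC reporting. Training is
#' deterministic for a given seed.
#'
#' @param pos Named list: per cell type, a character vector of positive
#'   sequences of the architecture's input length.
#' @param neg Character vector of (GC-matched) negative sequences.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @param arch Architecture from [regseq_config()].
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled L2 weight decay applied to weight (not
#'   bias) tensors each step.
#' @param dropout Training-time dropout rate on the flattened convolutional
#'   output and the dense hidden layer (0 disables).
#' @return An object of class `regseq_model` with elements `weights`,
#'   `arch`, `heads`, `holdout_auroc`, `loss` (per-epoch training loss).
#' @export
train_regseq <- function(pos, neg, epochs = 30L, seed = 1L,
                         arch = regseq_config(), lr = 3e-3, batch_size = 64L,
                         weight_decay = 1e-3, dropout = 0.25) {
  if (length(neg) == 0 || any(!vapply(pos, length, 0L))) {
    abort("every head needs sequences; got an empty class")
  }
  if (flat_len(arch) < arch$conv_filters[length(arch$conv_filters)]) {
    abort("input_len too short for this conv/pool geometry")
  }
  heads <- c(names(pos), "background")
  seqs <- c(unlist(pos, use.names = FALSE), neg)
  memb <- c(rep(names(pos), vapply(pos, length, 0L)), rep("background", length(neg)))
  Y <- outer(memb, heads, `==`) * 1
  X <- one_hot_dna(seqs)
  n <- length(seqs)

  withr::local_seed(seed)
  W <- init_weights(arch, seed)
  W$Wh <- matrix(rnorm(arch$dense * length(heads), sd = sqrt(2 / arch$dense)),
                 arch$dense, length(heads))
  W$bh <- numeric(length(heads))

  hold <- sample.int(n, max(2L, floor(0.2 * n)))
  tr <- setdiff(seq_len(n), hold)
  state <- list(m = list(), v = list())
  t <- 0L
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      dm <- NULL
      if (dropout > 0) {
        keep <- 1 - dropout
        dm <- list(
          mF = matrix(rbinom(length(b) * flat_len(arch), 1, keep) / keep,
                      length(b), flat_len(arch)),
          mH = matrix(rbinom(length(b) * arch$dense, 1, keep) / keep,
                      length(b), arch$dense))
      }
      fw <- net_forward(W, X[b, , , drop = FALSE], arch, keep_cache = TRUE,
                        dropout = dm)
      g <- net_backward(W, Y[b, , drop = FALSE], fw$probs, fw$cache, arch)
      t <- t + 1L
      st <- adam_step(W, g, state, lr, t, weight_decay = weight_decay)
      W <- st$W; state <- st$state
      ep_loss <- ep_loss + bce_loss(fw$probs, Y[b, , drop = FALSE])
      nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
  }
  ph <- net_predict(W, X[hold, , , drop = FALSE], arch)
  aucs <- vapply(seq_along(heads), function(h) {
    yh <- Y[hold, h]
    if (length(unique(yh)) < 2) return(NA_real_)
    auroc_u(ph[, h], yh)
  }, 0)
  structure(list(weights = W, arch = arch, heads = heads,
                 holdout_auroc = setNames(aucs, heads), loss = losses,
                 seed = seed),
            class = "regseq_model")
}

#' @export
print.regseq_model <- function(x, ...) {
  cat("<regseq_model> heads:", paste(x$heads, collapse = ", "), "\n")
  cat("  holdout AUROC:",
      paste(sprintf("%s=%.3f", x$heads, x$holdout_auroc), collapse = " "), "\n")
  invisible(x)
}

#' Predict per-head open-chromatin probabilities
#'
#' @param model A `regseq_model`.
#' @param seqs Character vector of sequences of the model's input length.
#' @return A numeric matrix, sequences by heads.
#' @export
predict_regseq <- function(model, seqs) {
  p <- net_predict(model$weights, one_hot_dna(seqs), model$arch)
  colnames(p) <- model$heads
  p
}

#' Regulatory variant effects
#'
#' For each variant, extracts the 500 bp reference window centered on the
#' variant, applies the alternative allele (indels shift the downstream
#' sequence; the window is re-centered on the edit and trimmed back to the
#' input length), and reports per-head probability deltas
#' `p(alt) - p(ref)` plus the derived summary features: the cell-type
#' agnostic mean delta, the maximum positive and minimum negative delta
#' over cell-type heads, and the background-head delta. Windows running
#' past a contig end are padded with `N` (zero channels).
#'
#' @param model A `regseq_model`.
#' @param reference Named character vector or `DNAStringSet`.
#' @param variants A variant tibble.
#' @return A tibble: variant keys, one `delta_<head>` column per head, and
#'   `reg_mean`, `reg_maxpos`, `reg_minneg`, `reg_background`.
#' @export
variant_effect <- function(model, reference, variants) {
  reference <- as_reference(reference)
  L <- model$arch$input_len
  half <- L %/% 2L
  win <- function(seq, center) {
    lo <- center - half + 1L
    hi <- lo + L - 1L
    padl <- max(0L, 1L - lo)
    padr <- max(0L, hi - nchar(seq))
    core <- substr(seq, max(1L, lo), min(nchar(seq), hi))
    paste0(strrep("N", padl), core, strrep("N", padr))
  }
  refw <- character(nrow(variants)); altw <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]; p <- variants$pos[i]
    n_ctg <- contig_len(reference, ctg)
    lo0 <- max(1L, p - L - 1L)          # work on a local slice, not the contig
    seq <- substr(reference[[ctg]], lo0, min(n_ctg, p + L + 1L))
    p <- p - lo0 + 1L
    r <- variants$ref[i]; a <- variants$alt[i]
    refw[i] <- win(seq, p)
    edited <- paste0(substr(seq, 1, p - 1L), a,
                     substr(seq, p + nchar(r), nchar(seq)))
    # re-center on the edit midpoint in edited coordinates
    center <- p + (nchar(a) - 1L) %/% 2L
    altw[i] <- win(edited, center)
  }
  pr <- predict_regseq(model, refw)
  pa <- predict_regseq(model, altw)
  delta <- pa - pr
  cell <- setdiff(model$heads, "background")
  out <- variants[, intersect(c("contig", "pos", "ref", "alt", "vclass"),
                              names(variants)), drop = FALSE]
  for (h in model$heads) out[[paste0("delta_", h)]] <- delta[, h]
  dc <- delta[, cell, drop = FALSE]
  out$reg_mean <- rowMeans(dc)
  out$reg_maxpos <- apply(pmax(dc, 0), 1, max)
  out$reg_minneg <- apply(pmin(dc, 0), 1, min)
  out$reg_background <- delta[, "background"]
  out
}
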