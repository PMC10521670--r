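# Internal layer primitives with hand-written backward passes.
#
# All activations are channel-row matrices (C x P, P = N*H*W, pixel index
# s = n*H*W + y*W + x). The arithmetic-heavy pieces (convolutions, batch
# norm, activations) live in the C++ kernels; point-wise convolutions are
# plain BLAS products on these matrices. Local-branch blocks use the fused
# batch-norm + leaky-ReLU kernels (which need slope > 0 to reconstruct the
# pre-activation in the backward pass); the global branch, whose
# rectification is a plain ReLU, uses the unfused path at its quarter
# resolution.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# batch statistics (or running statistics in eval mode) of one BN layer;
# updates the running stats in `state` when training
.bn_stats <- function(params, state, key, X, training) {
  if (training) {
    mom <- cpp_row_moments(X)
    mu <- as.numeric(mom$mean)
    v <- pmax(as.numeric(mom$var), 0)
    rs <- state$bn[[key]]
    if (is.null(rs)) rs <- list(mean = mu * 0, var = mu * 0 + 1)
    state$bn[[key]] <- list(
      mean = (1 - .bn_momentum) * rs$mean + .bn_momentum * mu,
      var = (1 - .bn_momentum) * rs$var + .bn_momentum * v
    )
  } else {
    rs <- state$bn[[key]]
    if (is.null(rs)) rs <- list(mean = numeric(nrow(X)),
                                var = rep(1, nrow(X)))
    mu <- rs$mean
    v <- rs$var
  }
  list(mu = mu, invstd = 1 / sqrt(v + .bn_eps),
       g = params[[paste0(key, ".gamma")]],
       b = params[[paste0(key, ".beta")]])
}

# unfused batch normalization (global branch)
.bn_fwd <- function(params, state, key, X, training) {
  s <- .bn_stats(params, state, key, X, training)
  ap <- cpp_bn_apply(X, s$mu, s$invstd, s$g, s$b)
  list(y = ap$y, cache = list(xhat = ap$xhat, invstd = s$invstd, g = s$g))
}

.bn_bwd <- function(dY, cache) {
  out <- cpp_bn_bwd(dY, cache$xhat, cache$invstd, cache$g)
  list(dX = out$dX, dgamma = as.numeric(out$dgamma),
       dbeta = as.numeric(out$dbeta))
}

.sigmoid <- function(X) 1 / (1 + exp(-X))

# separable convolution block: per-domain depth-wise 3x3 -> per-domain BN ->
# leaky ReLU -> shared point-wise 1x1 (+bias) -> shared BN -> leaky ReLU
.sep_fwd <- function(params, state, blk, dom, X, H, W, N, training, slope,
                     keep = FALSE) {
  dpre <- paste0("dom", dom, ".", blk)
  spre <- paste0("shared.", blk)
  W9 <- params[[paste0(dpre, ".dw.W")]]
  a <- cpp_dw3_fwd(X, W9, H, W, N)
  s1 <- .bn_stats(params, state, paste0(dpre, ".bn1"), a, training)
  h1 <- cpp_bn_lrelu_fwd(a, s1$mu, s1$invstd, s1$g, s1$b, slope)
  z <- params[[paste0(spre, ".pw.W")]] %*% h1 + params[[paste0(spre, ".pw.b")]]
  s2 <- .bn_stats(params, state, paste0(spre, ".bn2"), z, training)
  h2 <- cpp_bn_lrelu_fwd(z, s2$mu, s2$invstd, s2$g, s2$b, slope)
  cache <- if (keep)
    list(X = X, h1 = h1, y = h2, s1 = s1, s2 = s2,
         blk = blk, dom = dom, H = H, W = W, N = N)
  list(y = h2, cache = cache)
}

.sep_bwd <- function(params, dY, cache, gacc, slope) {
  dpre <- paste0("dom", cache$dom, ".", cache$blk)
  spre <- paste0("shared.", cache$blk)
  s2 <- cache$s2
  b2 <- cpp_bn_lrelu_bwd(dY, cache$y, s2$invstd, s2$g, s2$b, slope)
  .gadd(gacc, paste0(spre, ".bn2.gamma"), as.numeric(b2$dgamma))
  .gadd(gacc, paste0(spre, ".bn2.beta"), as.numeric(b2$dbeta))
  .gadd(gacc, paste0(spre, ".pw.W"), tcrossprod(b2$dX, cache$h1))
  .gadd(gacc, paste0(spre, ".pw.b"), rowSums(b2$dX))
  dh1 <- crossprod(params[[paste0(spre, ".pw.W")]], b2$dX)
  s1 <- cache$s1
  b1 <- cpp_bn_lrelu_bwd(dh1, cache$h1, s1$invstd, s1$g, s1$b, slope)
  .gadd(gacc, paste0(dpre, ".bn1.gamma"), as.numeric(b1$dgamma))
  .gadd(gacc, paste0(dpre, ".bn1.beta"), as.numeric(b1$dbeta))
  dw <- cpp_dw3_bwd(b1$dX, cache$X, params[[paste0(dpre, ".dw.W")]],
                    cache$H, cache$W, cache$N)
  .gadd(gacc, paste0(dpre, ".dw.W"), dw$dW)
  dw$dX
}

# standard 3x3 convolution block (U-Net baseline): conv (im2col + GEMM) ->
# BN -> leaky ReLU; all parameters shared
.std_fwd <- function(params, state, blk, X, H, W, N, training, slope,
                     keep = FALSE, dil = 1L) {
  spre <- paste0("shared.", blk)
  cols <- cpp_im2col3(X, H, W, N, dil)
  z <- params[[paste0(spre, ".conv.W")]] %*% cols + params[[paste0(spre, ".conv.b")]]
  s <- .bn_stats(params, state, paste0(spre, ".bn"), z, training)
  h <- cpp_bn_lrelu_fwd(z, s$mu, s$invstd, s$g, s$b, slope)
  cache <- if (keep)
    list(cols = cols, y = h, s = s, blk = blk,
         C = nrow(X), H = H, W = W, N = N, dil = dil)
  list(y = h, cache = cache)
}

.std_bwd <- function(params, dY, cache, gacc, slope) {
  spre <- paste0("shared.", cache$blk)
  s <- cache$s
  b <- cpp_bn_lrelu_bwd(dY, cache$y, s$invstd, s$g, s$b, slope)
  .gadd(gacc, paste0(spre, ".bn.gamma"), as.numeric(b$dgamma))
  .gadd(gacc, paste0(spre, ".bn.beta"), as.numeric(b$dbeta))
  .gadd(gacc, paste0(spre, ".conv.W"), tcrossprod(b$dX, cache$cols))
  .gadd(gacc, paste0(spre, ".conv.b"), rowSums(b$dX))
  dcols <- crossprod(params[[paste0(spre, ".conv.W")]], b$dX)
  cpp_col2im3(dcols, cache$C, cache$H, cache$W, cache$N, cache$dil)
}

# gradient accumulator (an environment so shared tensors can receive
# contributions from several paths)
.gnew <- function() new.env(parent = emptyenv())

.gadd <- function(gacc, name, val) {
  cur <- gacc[[name]]
  gacc[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

.gas_list <- function(gacc) as.list(gacc)
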