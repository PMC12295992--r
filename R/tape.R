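# Minimal reverse-mode autodiff tape. Nodes are environments carrying a
# value, parent links and a backward closure; creation order is the
# topological order, so backward() walks nodes in decreasing order of
# creation. Heavy ops (convolution, resizing, grid sampling) call the
# compiled kernels; everything else is vectorized R. Internal only.

.cx_env <- new.env(parent = emptyenv())
.cx_env$ord <- 0L

node_new <- function(val, parents = list(), bw = NULL,
                     requires = NULL) {
  if (is.null(requires)) {
    requires <- FALSE
    for (p in parents) if (p$requires) { requires <- TRUE; break }
  }
  e <- new.env(parent = emptyenv())
  .cx_env$ord <- .cx_env$ord + 1L
  e$ord <- .cx_env$ord
  e$val <- val
  e$parents <- parents
  e$bw <- bw
  e$requires <- requires
  e$grad <- NULL
  class(e) <- "cx_node"
  e
}

ag_const <- function(x) node_new(x, requires = FALSE)
ag_param <- function(x) node_new(x, requires = TRUE)
as_node <- function(x) if (inherits(x, "cx_node")) x else ag_const(x)

is_node <- function(x) inherits(x, "cx_node")

# Reduce a gradient to the shape of a (scalar) operand when it was
# broadcast against a larger array.
reduce_like <- function(g, val) {
  if (length(val) == 1L && length(g) > 1L) sum(g) else g
}

ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$val) == 1L)
  stack <- vector("list", 64L)
  stack[[1L]] <- loss
  top <- 1L
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  nn <- 0L
  while (top > 0L) {
    nd <- stack[[top]]
    top <- top - 1L
    key <- as.character(nd$ord)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    if (!nd$requires) next
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    nd$grad <- NULL
    for (p in nd$parents) {
      top <- top + 1L
      if (top > length(stack)) stack <- c(stack, vector("list", length(stack)))
      stack[[top]] <- p
    }
  }
  nodes <- nodes[seq_len(nn)]
  ords <- vapply(nodes, function(n) n$ord, integer(1))
  nodes <- nodes[order(ords, decreasing = TRUE)]
  loss$grad <- 1
  for (nd in nodes) {
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd, nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!p$requires || is.null(gs[[i]])) next
      if (is.null(p$grad)) p$grad <- gs[[i]] else p$grad <- p$grad + gs[[i]]
    }
  }
  invisible(loss)
}

# ---- elementwise ops --------------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  node_new(a$val + b$val, list(a, b), function(nd, g) {
    list(reduce_like(g, nd$parents[[1]]$val),
         reduce_like(g, nd$parents[[2]]$val))
  })
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  node_new(a$val - b$val, list(a, b), function(nd, g) {
    list(reduce_like(g, nd$parents[[1]]$val),
         reduce_like(-g, nd$parents[[2]]$val))
  })
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  node_new(a$val * b$val, list(a, b), function(nd, g) {
    list(reduce_like(g * nd$parents[[2]]$val, nd$parents[[1]]$val),
         reduce_like(g * nd$parents[[1]]$val, nd$parents[[2]]$val))
  })
}

ag_div <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  node_new(a$val / b$val, list(a, b), function(nd, g) {
    av <- nd$parents[[1]]$val; bv <- nd$parents[[2]]$val
    list(reduce_like(g / bv, av), reduce_like(-g * av / (bv * bv), bv))
  })
}

ag_neg <- function(a) ag_mul(a, -1)

ag_sum <- function(x) {
  x <- as_node(x)
  node_new(sum(x$val), list(x), function(nd, g) {
    v <- nd$parents[[1]]$val
    v[] <- g
    list(v)
  })
}

ag_mean <- function(x) {
  x <- as_node(x)
  n <- length(x$val)
  node_new(sum(x$val) / n, list(x), function(nd, g) {
    v <- nd$parents[[1]]$val
    v[] <- g / length(v)
    list(v)
  })
}

ag_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$val))
  node_new(s, list(x), function(nd, g) {
    s <- nd$val
    list(g * s * (1 - s))
  })
}

ag_tanh <- function(x) {
  x <- as_node(x)
  node_new(tanh(x$val), list(x), function(nd, g) list(g * (1 - nd$val^2)))
}

ag_relu <- function(x) {
  x <- as_node(x)
  node_new(pmax(x$val, 0), list(x), function(nd, g) {
    list(g * (nd$parents[[1]]$val > 0))
  })
}

ag_silu <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$val))
  y <- x$val * s
  node_new(y, list(x), function(nd, g) {
    xv <- nd$parents[[1]]$val
    s <- 1 / (1 + exp(-xv))
    list(g * s * (1 + xv * (1 - s)))
  })
}

ag_log_clamped <- function(x, eps = 1e-7) {
  x <- as_node(x)
  xc <- pmax(x$val, eps)
  node_new(log(xc), list(x), function(nd, g) {
    xv <- nd$parents[[1]]$val
    list(g * (xv >= eps) / pmax(xv, eps))
  })
}

ag_sqrt_eps <- function(x, eps = 1e-12) {
  x <- as_node(x)
  y <- sqrt(x$val + eps)
  node_new(y, list(x), function(nd, g) list(g * 0.5 / nd$val))
}

ag_clamp <- function(x, lo, hi) {
  x <- as_node(x)
  node_new(pmin(pmax(x$val, lo), hi), list(x), function(nd, g) {
    xv <- nd$parents[[1]]$val
    list(g * (xv >= lo & xv <= hi))
  })
}

ag_stopgrad <- function(x) {
  x <- as_node(x)
  node_new(x$val, list(), NULL, requires = FALSE)
}

# ---- volume ops (H, W, D, C arrays) -----------------------------------

ag_conv3d <- function(x, w, b, k, stride = 1L, pad = 1L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  v <- .cx_conv3d_fwd(x$val, dim(x$val), w$val, b$val, k, stride, pad)
  node_new(v, list(x, w, b), function(nd, g) {
    xn <- nd$parents[[1]]; wn <- nd$parents[[2]]
    r <- .cx_conv3d_bwd(xn$val, dim(xn$val), wn$val, g, k, stride, pad,
                        xn$requires)
    list(if (xn$requires) r$dx else NULL, r$dw, r$db)
  })
}

ag_dwconv3d <- function(x, w, b, k, stride = 1L, pad = 1L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  v <- .cx_dwconv3d_fwd(x$val, dim(x$val), w$val, b$val, k, stride, pad)
  node_new(v, list(x, w, b), function(nd, g) {
    xn <- nd$parents[[1]]; wn <- nd$parents[[2]]
    r <- .cx_dwconv3d_bwd(xn$val, dim(xn$val), wn$val, g, k, stride, pad)
    list(r$dx, r$dw, r$db)
  })
}

ag_resize3d <- function(x, odims) {
  x <- as_node(x)
  odims <- as.integer(odims)
  v <- .cx_resize3d_fwd(x$val, dim(x$val), odims)
  node_new(v, list(x), function(nd, g) {
    xn <- nd$parents[[1]]
    list(.cx_resize3d_bwd(g, dim(nd$val), dim(xn$val)))
  })
}

ag_concat_ch <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$val); db <- dim(b$val)
  v <- array(c(a$val, b$val), dim = c(da[1:3], da[4] + db[4]))
  node_new(v, list(a, b), function(nd, g) {
    da <- dim(nd$parents[[1]]$val); db <- dim(nd$parents[[2]]$val)
    na <- prod(da)
    ga <- array(g[seq_len(na)], dim = da)
    gb <- array(g[na + seq_len(prod(db))], dim = db)
    list(ga, gb)
  })
}

# global average pool over spatial dims -> length-C vector
ag_gap <- function(x) {
  x <- as_node(x)
  d <- dim(x$val)
  nv <- prod(d[1:3])
  v <- colMeans(matrix(x$val, nv, d[4]))
  node_new(v, list(x), function(nd, g) {
    d <- dim(nd$parents[[1]]$val)
    nv <- prod(d[1:3])
    list(array(rep(g / nv, each = nv), dim = d))
  })
}

# multiply each channel by a scalar (s: length-C vector)
ag_chscale <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  d <- dim(x$val)
  nv <- prod(d[1:3])
  v <- x$val * rep(s$val, each = nv)
  node_new(v, list(x, s), function(nd, g) {
    xv <- nd$parents[[1]]$val; sv <- nd$parents[[2]]$val
    d <- dim(xv); nv <- prod(d[1:3])
    gx <- g * rep(sv, each = nv)
    gs <- colSums(matrix(g * xv, nv, d[4]))
    list(array(gx, dim = d), gs)
  })
}

# instance normalization: per channel over spatial, affine per channel.
# A single-voxel spatial field cannot be normalized (zero variance);
# the affine map alone is applied there so the signal survives the
# coarsest stage.
ag_instnorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$val)
  nv <- prod(d[1:3])
  if (nv == 1L) {
    y <- x$val * rep(gamma$val, each = 1) + rep(beta$val, each = 1)
    return(node_new(array(y, dim = d), list(x, gamma, beta),
                    function(nd, g) {
                      xv <- nd$parents[[1]]$val
                      gam <- nd$parents[[2]]$val
                      list(array(g * gam, dim = dim(xv)),
                           as.numeric(g) * as.numeric(xv),
                           as.numeric(g))
                    }))
  }
  xm <- matrix(x$val, nv, d[4])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = nv)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = nv)
  y <- xhat * rep(gamma$val, each = nv) + rep(beta$val, each = nv)
  node_new(array(y, dim = d), list(x, gamma, beta), function(nd, g) {
    xv <- nd$parents[[1]]$val
    gam <- nd$parents[[2]]$val
    d <- dim(xv); nv <- prod(d[1:3])
    xm <- matrix(xv, nv, d[4])
    gm <- matrix(g, nv, d[4])
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = nv)
    va <- colMeans(xc * xc)
    istd <- 1 / sqrt(va + eps)
    xhat <- xc * rep(istd, each = nv)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(gam, each = nv)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = nv) - xhat * rep(m2, each = nv)) *
      rep(istd, each = nv)
    list(array(dx, dim = d), dgamma, dbeta)
  })
}

# ---- point / matrix ops ----------------------------------------------

ag_mm <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  node_new(a$val %*% b$val, list(a, b), function(nd, g) {
    list(g %*% t(nd$parents[[2]]$val), crossprod(nd$parents[[1]]$val, g))
  })
}

ag_addrow <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  node_new(sweep(x$val, 2, b$val, `+`), list(x, b), function(nd, g) {
    list(g, colSums(g))
  })
}

# layer norm per row over columns, affine per column
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xm <- x$val
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2, gamma$val, `*`), 2, beta$val, `+`)
  node_new(y, list(x, gamma, beta), function(nd, g) {
    xm <- nd$parents[[1]]$val
    gam <- nd$parents[[2]]$val
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    istd <- 1 / sqrt(va + eps)
    xhat <- xc * istd
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2, gam, `*`)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) * istd
    list(dx, dgamma, dbeta)
  })
}

ag_gather <- function(x, idx) {
  x <- as_node(x)
  idx <- as.integer(idx)
  node_new(x$val[idx, , drop = FALSE], list(x), function(nd, g) {
    xv <- nd$parents[[1]]$val
    gx <- matrix(0, nrow(xv), ncol(xv))
    agg <- rowsum(g, group = idx)
    gx[as.integer(rownames(agg)), ] <- agg
    list(gx)
  })
}

ag_cols <- function(x, idx) {
  x <- as_node(x)
  idx <- as.integer(idx)
  node_new(x$val[, idx, drop = FALSE], list(x), function(nd, g) {
    xv <- nd$parents[[1]]$val
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, idx] <- gx[, idx] + g
    list(gx)
  })
}

ag_cbind2 <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  node_new(cbind(a$val, b$val), list(a, b), function(nd, g) {
    na <- ncol(nd$parents[[1]]$val)
    list(g[, seq_len(na), drop = FALSE],
         g[, -seq_len(na), drop = FALSE])
  })
}

ag_rowsums <- function(x) {
  x <- as_node(x)
  node_new(rowSums(x$val), list(x), function(nd, g) {
    xv <- nd$parents[[1]]$val
    list(matrix(g, nrow(xv), ncol(xv)))
  })
}

ag_reshape <- function(x, newdim) {
  x <- as_node(x)
  v <- x$val
  dim(v) <- newdim
  node_new(v, list(x), function(nd, g) {
    dim(g) <- dim(nd$parents[[1]]$val)
    list(g)
  })
}

# trilinear sampling of a (H, W, D, C) map at M normalized coords (M x 3)
ag_gridsample <- function(fmap, coords) {
  fmap <- as_node(fmap); coords <- as_node(coords)
  v <- .cx_gridsample_fwd(fmap$val, dim(fmap$val), coords$val)
  node_new(v, list(fmap, coords), function(nd, g) {
    fn <- nd$parents[[1]]; cn <- nd$parents[[2]]
    r <- .cx_gridsample_bwd(fn$val, dim(fn$val), cn$val, g)
    list(r$dx, r$dcoords)
  })
}
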