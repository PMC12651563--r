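# Minimal CPU neural-network core: mutable module objects (environments)
# with explicit forward/backward passes.  Convolutions run through the
# compiled im2col/GEMM kernels; everything else is vectorised R.
#
# Layout contract: activations (H, W, C, N); conv weights (kh, kw, Cin, Cout).

new_mod <- function(kind, name = kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$name <- name
  e$path <- name
  e$children <- list()
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$cache <- NULL
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(paste0("nn_", kind), "nn_module")
  e
}

make_ctx <- function(training = FALSE, grad = training, hooks = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$training <- training
  ctx$grad <- grad
  ctx$hooks <- hooks
  ctx
}

make_hooks <- function(targets) {
  h <- new.env(parent = emptyenv())
  h$targets <- targets
  h$acts <- new.env(parent = emptyenv())
  h$grads <- new.env(parent = emptyenv())
  h
}

# Dispatch tables (filled at load time) avoid S3 method lookup on the hot
# path; methods keep the conventional nn_fw.nn_<kind> naming.
.dispatch <- new.env(parent = emptyenv())

build_dispatch <- function() {
  ns <- parent.env(environment())
  kinds <- c("conv", "bn", "relu", "sigmoid", "upsample", "seq", "cbam",
             "cbres", "dual_dilate", "tridilation", "splitfusion", "mu",
             "munet")
  for (k in kinds) {
    .dispatch[[paste0("fw_", k)]] <- get(paste0("nn_fw.nn_", k), envir = ns)
    .dispatch[[paste0("bw_", k)]] <- get(paste0("nn_bw.nn_", k), envir = ns)
    .dispatch[[paste0("ct_", k)]] <- get(paste0("nn_count.nn_", k), envir = ns)
  }
}

nn_fw <- function(mod, x, ctx) .dispatch[[paste0("fw_", mod$kind)]](mod, x, ctx)
nn_bw <- function(mod, dy, ctx) .dispatch[[paste0("bw_", mod$kind)]](mod, dy, ctx)
nn_count <- function(mod, shape, acc)
  .dispatch[[paste0("ct_", mod$kind)]](mod, shape, acc)

# Wrappers adding activation/gradient capture for named layers (Grad-CAM).
nn_forward <- function(mod, x, ctx) {
  y <- nn_fw(mod, x, ctx)
  if (!is.null(ctx$hooks)) {
    hooked <- mod$path %in% ctx$hooks$targets
    if (hooked) assign(mod$path, y, envir = ctx$hooks$acts)
    mod$.hooked <- hooked
  }
  y
}

nn_backward <- function(mod, dy, ctx) {
  if (!is.null(ctx$hooks) && isTRUE(mod$.hooked))
    assign(mod$path, dy, envir = ctx$hooks$grads)
  nn_bw(mod, dy, ctx)
}

# Depth-first list of a module and all descendants.
nn_modules <- function(mod) {
  out <- list(mod)
  for (ch in mod$children) out <- c(out, nn_modules(ch))
  out
}

assign_paths <- function(mod, prefix = mod$name) {
  mod$path <- prefix
  for (i in seq_along(mod$children)) {
    ch <- mod$children[[i]]
    nm <- names(mod$children)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- ch$name
    assign_paths(ch, paste(prefix, nm, sep = "/"))
  }
  invisible(mod)
}

nn_zero_grad <- function(model) {
  for (m in nn_modules(model)) ensure_grads(m, zero = TRUE)
  invisible(model)
}

ensure_grads <- function(mod, zero = FALSE) {
  if (is.null(mod$.has_grads)) {
    for (nm in names(mod$params))
      if (is.null(mod$grads[[nm]])) mod$grads[[nm]] <- mod$params[[nm]] * 0
    mod$.has_grads <- TRUE
  } else if (zero) {
    for (g in mod$grads) fill_zero_cpp(g)
  }
  invisible(mod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# In-place gradient accumulation; gradient buffers live as long as the
# module and are zeroed (not reallocated) at each optimisation step.
accum_grad <- function(mod, name, g) {
  if (is.null(mod$grads[[name]])) mod$grads[[name]] <- mod$params[[name]] * 0
  axpy_cpp(mod$grads[[name]], g)
  invisible(NULL)
}

n_params <- function(model) {
  sum(vapply(nn_modules(model),
             function(m) sum(vapply(m$params, length, 0L)), 0))
}

# Weight state (parameters + batch-norm running statistics), keyed by path.
# Arrays are copied: optimisation updates parameters in place, so snapshots
# must not share memory with the live model.
get_weights <- function(model) {
  st <- list()
  deep <- function(l) lapply(l, function(p) p + 0)
  for (m in nn_modules(model))
    if (length(m$params) || length(m$buffers))
      st[[m$path]] <- list(params = deep(m$params), buffers = deep(m$buffers))
  st
}

set_weights <- function(model, st) {
  for (m in nn_modules(model)) {
    s <- st[[m$path]]
    if (!is.null(s)) {
      stopifnot(identical(lapply(m$params, dim), lapply(s$params, dim)))
      m$params <- lapply(s$params, function(p) p + 0)
      m$buffers <- lapply(s$buffers, function(p) p + 0)
    }
  }
  invisible(model)
}

# ---- convolution -----------------------------------------------------------

same_pad <- function(n, k, stride, dil) {
  out <- as.integer(ceiling(n / stride))
  tot <- max(0L, (out - 1L) * stride + (k - 1L) * dil + 1L - n)
  c(out = out, pad = tot %/% 2L)
}

nn_conv <- function(in_ch, out_ch, kh, kw = kh, stride = 1L, dilation = 1L,
                    init = c("he", "zero"), name = "conv") {
  init <- match.arg(init)
  std <- sqrt(2 / (kh * kw * in_ch))
  w <- if (init == "he") array(rnorm(kh * kw * in_ch * out_ch, 0, std),
                               c(kh, kw, in_ch, out_ch))
       else array(0, c(kh, kw, in_ch, out_ch))
  new_mod("conv", name = name, in_ch = as.integer(in_ch),
          out_ch = as.integer(out_ch), kh = as.integer(kh), kw = as.integer(kw),
          stride = as.integer(stride), dilation = as.integer(dilation),
          params = list(w = w, b = double(out_ch)))
}

nn_fw.nn_conv <- function(mod, x, ctx) {
  d <- dim(x)
  geo <- mod$.geo
  if (is.null(geo) || geo[1L] != d[1L] || geo[2L] != d[2L]) {
    ph <- same_pad(d[1L], mod$kh, mod$stride, mod$dilation)
    pw <- same_pad(d[2L], mod$kw, mod$stride, mod$dilation)
    geo <- c(d[1L], d[2L], ph[["pad"]], pw[["pad"]], ph[["out"]], pw[["out"]])
    mod$.geo <- geo
  }
  r <- conv2d_fw_cpp(x, mod$params$w, mod$params$b, mod$stride,
                     mod$dilation, mod$dilation, geo[3L], geo[4L],
                     geo[5L], geo[6L], want_col = FALSE)
  if (ctx$grad)
    mod$cache <- list(x = x, pad = geo[3:4], col = matrix(0, 0L, 0L))
  r$y
}

nn_bw.nn_conv <- function(mod, dy, ctx) {
  cc <- mod$cache
  ensure_grads(mod)
  conv2d_bw_cpp(cc$x, mod$params$w, dy, mod$stride,
                mod$dilation, mod$dilation, cc$pad[1L], cc$pad[2L],
                mod$grads$w, mod$grads$b, cc$col)
}

# ---- batch normalisation ---------------------------------------------------

# identity = TRUE freezes the layer to a pass-through (test hook for the
# exact block oracles); momentum follows running <- m*running + (1-m)*batch.
nn_bn <- function(channels, momentum = 0.9, eps = 1e-5, identity = FALSE,
                  name = "bn") {
  new_mod("bn", name = name, channels = as.integer(channels),
          momentum = momentum, eps = eps, identity = identity,
          params = list(gamma = rep(1, channels), beta = rep(0, channels)),
          buffers = list(rm = rep(0, channels), rv = rep(1, channels)))
}

nn_fw.nn_bn <- function(mod, x, ctx) {
  if (isTRUE(mod$identity)) {
    if (ctx$grad) mod$cache <- list(identity = TRUE)
    return(x)
  }
  r <- bn_fw_cpp(x, mod$params$gamma, mod$params$beta, ctx$training,
                 mod$buffers$rm, mod$buffers$rv, mod$momentum, mod$eps,
                 want_cache = ctx$grad)
  if (ctx$grad)
    mod$cache <- list(identity = FALSE, x = x, mu = r$mu, invstd = r$invstd,
                      batch_stats = ctx$training)
  r$y
}

nn_bw.nn_bn <- function(mod, dy, ctx) {
  cc <- mod$cache
  if (isTRUE(cc$identity)) return(dy)
  ensure_grads(mod)
  bn_bw_cpp(dy, cc$x, cc$mu, cc$invstd, mod$params$gamma, cc$batch_stats,
            mod$grads$gamma, mod$grads$beta)
}

# ---- pointwise activations -------------------------------------------------

nn_relu <- function(name = "relu") new_mod("relu", name = name)

nn_fw.nn_relu <- function(mod, x, ctx) {
  y <- relu_fw_cpp(x)
  if (ctx$grad) mod$cache <- list(y = y)
  y
}

nn_bw.nn_relu <- function(mod, dy, ctx) relu_bw_cpp(dy, mod$cache$y)

nn_sigmoid <- function(name = "sigmoid") new_mod("sigmoid", name = name)

nn_fw.nn_sigmoid <- function(mod, x, ctx) {
  y <- sigmoid(x)
  if (ctx$grad) mod$cache <- list(y = y)
  y
}

nn_bw.nn_sigmoid <- function(mod, dy, ctx) dy * mod$cache$y * (1 - mod$cache$y)

# ---- nearest-neighbour 2x upsampling --------------------------------------

nn_upsample <- function(name = "up") new_mod("upsample", name = name)

nn_fw.nn_upsample <- function(mod, x, ctx) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

nn_bw.nn_upsample <- function(mod, dy, ctx) {
  d <- dim(dy)
  o1 <- seq(1L, d[1L], 2L); e1 <- seq(2L, d[1L], 2L)
  o2 <- seq(1L, d[2L], 2L); e2 <- seq(2L, d[2L], 2L)
  dy[o1, o2, , , drop = FALSE] + dy[e1, o2, , , drop = FALSE] +
    dy[o1, e2, , , drop = FALSE] + dy[e1, e2, , , drop = FALSE]
}

# ---- sequential container --------------------------------------------------

nn_seq <- function(children, name = "seq") {
  m <- new_mod("seq", name = name)
  m$children <- children
  m
}

nn_fw.nn_seq <- function(mod, x, ctx) {
  for (ch in mod$children) x <- nn_forward(ch, x, ctx)
  x
}

nn_bw.nn_seq <- function(mod, dy, ctx) {
  for (ch in rev(mod$children)) dy <- nn_backward(ch, dy, ctx)
  dy
}

# ---- AdamW optimiser -------------------------------------------------------

adamw_new <- function(model, lr = 1e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$wd <- weight_decay
  opt$b1 <- beta1; opt$b2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- list(); opt$v <- list()
  opt$model <- model
  opt
}

# Parameters, moments and gradients are updated in place (they are owned
# exclusively by the model; snapshots taken via get_weights() are copies).
adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (mod in nn_modules(opt$model)) {
    for (nm in names(mod$params)) {
      key <- paste(mod$path, nm, sep = ":")
      g <- mod$grads[[nm]]
      if (is.null(g)) next
      if (is.null(opt$m[[key]])) {
        opt$m[[key]] <- g * 0
        opt$v[[key]] <- g * 0
      }
      adamw_update_cpp(mod$params[[nm]], g, opt$m[[key]], opt$v[[key]],
                       opt$lr, opt$wd, opt$b1, opt$b2, opt$eps, bc1, bc2)
    }
  }
  invisible(opt)
}

# ---- shape / parameter / FLOP accounting ----------------------------------

# acc: environment collecting one row per parameterised or compute layer.
new_count_acc <- function() {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  acc$add <- function(path, kind, shape, params, flops) {
    acc$rows[[length(acc$rows) + 1L]] <-
      data.frame(layer = path, type = kind,
                 out_shape = paste(shape, collapse = "x"),
                 params = params, flops = flops, stringsAsFactors = FALSE)
  }
  acc
}

# Returns the output shape; records params and forward FLOPs in acc.
# Convolution FLOPs: 2*kh*kw*Cin*Cout*Hout*Wout (one MAC = 2 FLOPs);
# normalisation, activations, pooling and resampling count 1 op/element.
nn_count.nn_conv <- function(mod, shape, acc) {
  ph <- same_pad(shape[1L], mod$kh, mod$stride, mod$dilation)
  pw <- same_pad(shape[2L], mod$kw, mod$stride, mod$dilation)
  out <- c(ph[["out"]], pw[["out"]], mod$out_ch, shape[4L])
  fl <- 2 * mod$kh * mod$kw * mod$in_ch * mod$out_ch *
    out[1L] * out[2L] * out[4L] + prod(out)
  acc$add(mod$path, "conv", out, length(mod$params$w) + length(mod$params$b), fl)
  out
}

nn_count.nn_bn <- function(mod, shape, acc) {
  acc$add(mod$path, "bn", shape, 2L * mod$channels, prod(shape))
  shape
}

nn_count.nn_relu <- function(mod, shape, acc) {
  acc$add(mod$path, "relu", shape, 0L, prod(shape))
  shape
}

nn_count.nn_sigmoid <- function(mod, shape, acc) {
  acc$add(mod$path, "sigmoid", shape, 0L, prod(shape))
  shape
}

nn_count.nn_upsample <- function(mod, shape, acc) {
  out <- c(shape[1L] * 2L, shape[2L] * 2L, shape[3L], shape[4L])
  acc$add(mod$path, "upsample", out, 0L, prod(out))
  out
}

nn_count.nn_seq <- function(mod, shape, acc) {
  for (ch in mod$children) shape <- nn_count(ch, shape, acc)
  shape
}
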