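# Model construction and the full forward/backward passes.
#
# Architecture (Enformer lineage, simplified):
#   stem conv (k=15) + residual pointwise conv + pool
#   -> conv tower blocks: LN-GELU-conv(k=5) + residual pointwise + pool
#   -> pre-norm attention blocks: x + MHA(LN(x)); x + FFN(LN(x))
#   -> optional final pointwise conv (LN-GELU-conv(k=1) to 2x width, GELU)
#   -> central crop -> linear head -> softplus rates.
#
# Ablation flags structurally remove layers: with use_attention_linear FALSE
# the linear at attention_linear_site does not exist in the parameter set
# (output projection gone -> concatenated heads feed the residual directly;
# ffn_second gone -> the feed-forward is a single C->C linear plus GELU).

# ---- parameter specification ----------------------------------------------

# Named list of parameter descriptors: dim, init ("kaiming", "ones", "zeros",
# "pool") and fan-in for the uniform bound.
param_spec <- function(cfg) {
  sp <- list()
  add <- function(name, dim, init = "kaiming", fan = NULL) {
    sp[[name]] <<- list(dim = dim, init = init, fan = fan)
  }
  widths <- conv_widths(cfg)
  cin <- 4L
  for (i in seq_len(cfg$num_conv_blocks)) {
    p <- function(part) sprintf("trunk.conv%d.%s", i, part)
    k <- if (i == 1L) 15L else 5L
    cout <- widths[i]
    if (i > 1L) {
      add(p("ln.g"), cin, "ones"); add(p("ln.b"), cin, "zeros")
    }
    add(p("main.W"), c(k * cin, cout), fan = k * cin)
    add(p("main.b"), cout, fan = k * cin)
    add(p("res.ln.g"), cout, "ones"); add(p("res.ln.b"), cout, "zeros")
    add(p("res.W"), c(cout, cout), fan = cout)
    add(p("res.b"), cout, fan = cout)
    if (i <= cfg$num_pooling_stages && cfg$pool_type == "attention") {
      add(p("pool.w"), cout, "pool")
    }
    cin <- cout
  }
  C <- cfg$model_width
  hd <- cfg$num_heads * cfg$head_dim
  has_proj <- cfg$use_attention_linear || cfg$attention_linear_site != "output_projection"
  two_ffn  <- cfg$use_attention_linear || cfg$attention_linear_site != "ffn_second"
  n_pos <- cfg$sequence_length %/% cfg$bin_size
  for (j in seq_len(cfg$num_attention_blocks)) {
    p <- function(part) sprintf("trunk.attn%d.%s", j, part)
    add(p("ln1.g"), C, "ones"); add(p("ln1.b"), C, "zeros")
    add(p("ln2.g"), C, "ones"); add(p("ln2.b"), C, "zeros")
    for (w in c("Wq", "Wk", "Wv")) add(p(w), c(C, hd), fan = C)
    for (b in c("bq", "bk", "bv")) add(p(b), hd, fan = C)
    if (cfg$positional_scheme == "learned_relative") add(p("pos"), c(n_pos, cfg$num_heads), "zeros")
    if (cfg$positional_scheme == "relative_bias")    add(p("pos"), c(8L, cfg$num_heads), "zeros")
    if (has_proj) {
      add(p("Wo"), c(hd, C), fan = hd); add(p("bo"), C, fan = hd)
    }
    dff <- if (two_ffn) 2L * C else C
    add(p("W1"), c(C, dff), fan = C); add(p("b1"), dff, fan = C)
    if (two_ffn) {
      add(p("W2"), c(dff, C), fan = dff); add(p("b2"), C, fan = dff)
    }
  }
  head_in <- C
  if (cfg$use_final_pointwise) {
    add("trunk.final.ln.g", C, "ones"); add("trunk.final.ln.b", C, "zeros")
    add("trunk.final.W", c(C, 2L * C), fan = C)
    add("trunk.final.b", 2L * C, fan = C)
    head_in <- 2L * C
  }
  add("head.W", c(head_in, cfg$num_tracks), fan = head_in)
  add("head.b", cfg$num_tracks, fan = head_in)
  sp
}

init_one <- function(d) {
  n <- prod(d$dim)
  v <- switch(d$init,
    ones  = rep(1, n),
    zeros = rep(0, n),
    pool  = rep(2, n),   # softmax pooling logit scale, Enformer convention
    kaiming = {
      bound <- 1 / sqrt(d$fan)
      stats::runif(n, -bound, bound)
    })
  if (length(d$dim) > 1L) array(v, d$dim) else v
}

init_params <- function(cfg, seed, spec = param_spec(cfg)) {
  withr::with_seed(seed, lapply(spec, init_one))
}

# ---- precomputed static data (index vectors, distance maps) ----------------

model_static <- function(cfg) {
  st <- list(conv = list())
  L <- cfg$sequence_length
  for (i in seq_len(cfg$num_conv_blocks)) {
    k <- if (i == 1L) 15L else 5L
    st$conv[[i]] <- list(L = L, iv = conv_iv(L, k))
    if (i <= cfg$num_pooling_stages) L <- L %/% 2L
  }
  st$n_pos <- L
  if (cfg$num_attention_blocks > 0L && cfg$positional_scheme != "none") {
    D <- abs(outer(seq_len(L), seq_len(L), "-")) + 1L
    st$dvec <- as.vector(D)
    if (cfg$positional_scheme == "relative_bias") {
      # symmetric exponential-decay basis over distances, log-spaced scales
      dist <- 0:(L - 1L)
      taus <- exp(seq(log(1), log(max(2, L / 2)), length.out = 8L))
      st$Fb <- sapply(taus, function(tau) exp(-dist / tau))
    }
  }
  st
}

# ---- construction ----------------------------------------------------------

#' Build a sequence-to-track model
#'
#' Constructs the network described by `config` with weights drawn
#' reproducibly from `seed` (uniform Kaiming-style bounds, the framework
#' default the training protocol assumes). Ablation flags remove layers
#' structurally: the corresponding parameters do not exist.
#'
#' @param config An [architecture_config()].
#' @param seed Integer seed controlling all weight initialization.
#' @return An object of class `s2t_model`: list with `config`, `params`
#'   (flat named list of arrays, names prefixed `trunk.` / `head.`),
#'   `static` precomputations, and `frozen_trunk` flag.
#' @export
build_model <- function(config, seed = 1L) {
  validate_config(config)
  spec <- param_spec(config)
  model <- list(
    config = config,
    params = init_params(config, seed, spec),
    static = model_static(config),
    frozen_trunk = FALSE,
    seed = as.integer(seed)
  )
  class(model) <- "s2t_model"
  model
}

#' @export
print.s2t_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<s2t_model> %d bp -> %d bins x %d tracks | conv %d (pool %d) attn %d width %d | %s params%s\n",
    cfg$sequence_length, cfg$output_bins, cfg$num_tracks,
    cfg$num_conv_blocks, cfg$num_pooling_stages, cfg$num_attention_blocks,
    cfg$model_width, format(count_parameters(x), big.mark = ","),
    if (x$frozen_trunk) " | trunk frozen" else ""))
  invisible(x)
}

#' Count model parameters
#'
#' @param model An `s2t_model`.
#' @param group `"all"`, `"trunk"` or `"head"`.
#' @return Integer count of scalar parameters in the group.
#' @export
count_parameters <- function(model, group = c("all", "trunk", "head")) {
  group <- match.arg(group)
  nm <- names(model$params)
  keep <- switch(group,
    all = rep(TRUE, length(nm)),
    trunk = startsWith(nm, "trunk."),
    head = startsWith(nm, "head."))
  sum(vapply(model$params[keep], length, integer(1)))
}

# ---- forward ---------------------------------------------------------------

check_input <- function(model, x) {
  L <- model$config$sequence_length
  if (!is.matrix(x) || ncol(x) != 4L || nrow(x) != L) {
    stop(errorCondition(
      sprintf("input shape mismatch: expected (%d, 4), got (%s)",
              L, paste(dim(x), collapse = ", ")),
      class = c("s2t_shape_error", "error")))
  }
}

# Forward pass for one example. keep_cache = TRUE retains every intermediate
# needed by model_backward; dropout is active only when train = TRUE.
model_forward_one <- function(model, x, train = FALSE, keep_cache = FALSE) {
  P <- model$params; cfg <- model$config; st <- model$static
  rate <- if (train) cfg$dropout_rate else 0
  CC <- if (keep_cache) list(conv = list(), attn = list()) else NULL
  h <- x
  for (i in seq_len(cfg$num_conv_blocks)) {
    p <- function(part) sprintf("trunk.conv%d.%s", i, part)
    cb <- list()
    if (i == 1L) {
      cv <- conv_fwd(h, P[[p("main.W")]], P[[p("main.b")]], 15L, st$conv[[i]]$iv)
    } else {
      ln <- layernorm_fwd(h, P[[p("ln.g")]], P[[p("ln.b")]])
      ge <- gelu_fwd(ln$y)
      cv <- conv_fwd(ge$y, P[[p("main.W")]], P[[p("main.b")]], 5L, st$conv[[i]]$iv)
      cb$ln <- ln; cb$ge <- ge
    }
    ln2 <- layernorm_fwd(cv$y, P[[p("res.ln.g")]], P[[p("res.ln.b")]])
    ge2 <- gelu_fwd(ln2$y)
    cv2 <- conv_fwd(ge2$y, P[[p("res.W")]], P[[p("res.b")]], 1L, NULL)
    h2 <- cv2$y + cv$y
    if (i <= cfg$num_pooling_stages) {
      if (cfg$pool_type == "attention") {
        pl <- pool_attn_fwd(h2, P[[p("pool.w")]])
      } else {
        pl <- pool_max_fwd(h2)
      }
      h <- pl$y
    } else pl <- NULL
    if (keep_cache) {
      cb$cv <- cv; cb$ln2 <- ln2; cb$ge2 <- ge2; cb$cv2 <- cv2; cb$pl <- pl
      CC$conv[[i]] <- cb
    }
    h <- if (!is.null(pl)) pl$y else h2
  }
  has_proj <- cfg$use_attention_linear || cfg$attention_linear_site != "output_projection"
  two_ffn  <- cfg$use_attention_linear || cfg$attention_linear_site != "ffn_second"
  for (j in seq_len(cfg$num_attention_blocks)) {
    p <- function(part) sprintf("trunk.attn%d.%s", j, part)
    ab <- list()
    ln1 <- layernorm_fwd(h, P[[p("ln1.g")]], P[[p("ln1.b")]])
    mh <- mha_fwd(ln1$y, P, p, cfg, st)
    O <- mh$O
    if (has_proj) {
      pr <- linear_fwd(O, P[[p("Wo")]], P[[p("bo")]])
      O <- pr$y
    } else pr <- NULL
    do1 <- dropout_fwd(O, rate)
    h1 <- h + do1$y
    ln2 <- layernorm_fwd(h1, P[[p("ln2.g")]], P[[p("ln2.b")]])
    l1 <- linear_fwd(ln2$y, P[[p("W1")]], P[[p("b1")]])
    ge <- gelu_fwd(l1$y)
    if (two_ffn) {
      l2 <- linear_fwd(ge$y, P[[p("W2")]], P[[p("b2")]])
      Fo <- l2$y
    } else { l2 <- NULL; Fo <- ge$y }
    do2 <- dropout_fwd(Fo, rate)
    h <- h1 + do2$y
    if (keep_cache) {
      ab$ln1 <- ln1; ab$mh <- mh; ab$pr <- pr; ab$do1 <- do1
      ab$ln2 <- ln2; ab$l1 <- l1; ab$ge <- ge; ab$l2 <- l2; ab$do2 <- do2
      CC$attn[[j]] <- ab
    }
  }
  if (cfg$use_final_pointwise) {
    fln <- layernorm_fwd(h, P[["trunk.final.ln.g"]], P[["trunk.final.ln.b"]])
    fge <- gelu_fwd(fln$y)
    fcv <- conv_fwd(fge$y, P[["trunk.final.W"]], P[["trunk.final.b"]], 1L, NULL)
    fge2 <- gelu_fwd(fcv$y)
    h <- fge2$y
    if (keep_cache) CC$final <- list(fln = fln, fge = fge, fcv = fcv, fge2 = fge2)
  }
  crop <- crop_per_side(cfg)
  rows <- (crop + 1L):(nrow(h) - crop)
  hc <- h[rows, , drop = FALSE]
  hd <- linear_fwd(hc, P[["head.W"]], P[["head.b"]])
  sp <- softplus_fwd(hd$y)
  if (keep_cache) {
    CC$head <- list(hd = hd, sp = sp, rows = rows, n_pos_full = nrow(h))
  }
  list(rates = sp$y, cache = CC)
}

#' Run the model forward
#'
#' Computes strictly positive per-bin rate predictions for one or more
#' one-hot encoded sequences. Evaluation mode: dropout is inactive, so the
#' output is deterministic given fixed parameters.
#'
#' @param model An `s2t_model`.
#' @param batch A single `(sequence_length, 4)` one-hot matrix or a list of
#'   them.
#' @return For a single matrix input, one `(output_bins, num_tracks)` rate
#'   matrix; for a list input, a list of such matrices.
#' @export
forward <- function(model, batch) {
  single <- is.matrix(batch)
  if (single) batch <- list(batch)
  out <- lapply(batch, function(x) {
    check_input(model, x)
    model_forward_one(model, x, train = FALSE, keep_cache = FALSE)$rates
  })
  if (single) out[[1]] else out
}

# ---- backward --------------------------------------------------------------

# Gradient of the forward pass wrt all parameters given d(loss)/d(rates).
# Returns a flat named list aligned with model$params.
model_backward_one <- function(model, cache, drates) {
  P <- model$params; cfg <- model$config; st <- model$static
  G <- list()
  addg <- function(name, g) G[[name]] <<- if (is.null(G[[name]])) g else G[[name]] + g
  hc <- cache$head
  dz <- softplus_bwd(drates, hc$sp)
  lb <- linear_bwd(dz, hc$hd, P[["head.W"]])
  addg("head.W", lb$dW); addg("head.b", lb$db)
  dh <- matrix(0, hc$n_pos_full, ncol(lb$dx))
  dh[hc$rows, ] <- lb$dx
  if (cfg$use_final_pointwise) {
    fc <- cache$final
    d1 <- gelu_bwd(dh, fc$fge2)
    cb <- conv_bwd(d1, fc$fcv, P[["trunk.final.W"]])
    addg("trunk.final.W", cb$dW); addg("trunk.final.b", cb$db)
    d2 <- gelu_bwd(cb$dx, fc$fge)
    lnb <- layernorm_bwd(d2, fc$fln, P[["trunk.final.ln.g"]])
    addg("trunk.final.ln.g", lnb$dg); addg("trunk.final.ln.b", lnb$db)
    dh <- lnb$dx
  }
  has_proj <- cfg$use_attention_linear || cfg$attention_linear_site != "output_projection"
  two_ffn  <- cfg$use_attention_linear || cfg$attention_linear_site != "ffn_second"
  for (j in rev(seq_len(cfg$num_attention_blocks))) {
    p <- function(part) sprintf("trunk.attn%d.%s", j, part)
    ab <- cache$attn[[j]]
    dFo <- dropout_bwd(dh, ab$do2)
    if (two_ffn) {
      lb2 <- linear_bwd(dFo, ab$l2, P[[p("W2")]])
      addg(p("W2"), lb2$dW); addg(p("b2"), lb2$db)
      dge <- lb2$dx
    } else dge <- dFo
    dl1 <- gelu_bwd(dge, ab$ge)
    lb1 <- linear_bwd(dl1, ab$l1, P[[p("W1")]])
    addg(p("W1"), lb1$dW); addg(p("b1"), lb1$db)
    lnb2 <- layernorm_bwd(lb1$dx, ab$ln2, P[[p("ln2.g")]])
    addg(p("ln2.g"), lnb2$dg); addg(p("ln2.b"), lnb2$db)
    dh1 <- dh + lnb2$dx
    dO <- dropout_bwd(dh1, ab$do1)
    if (has_proj) {
      pb <- linear_bwd(dO, ab$pr, P[[p("Wo")]])
      addg(p("Wo"), pb$dW); addg(p("bo"), pb$db)
      dO <- pb$dx
    }
    mb <- mha_bwd(dO, ab$mh, P, p, cfg, st)
    for (nmg in names(mb$grads)) addg(nmg, mb$grads[[nmg]])
    lnb1 <- layernorm_bwd(mb$da, ab$ln1, P[[p("ln1.g")]])
    addg(p("ln1.g"), lnb1$dg); addg(p("ln1.b"), lnb1$db)
    dh <- dh1 + lnb1$dx
  }
  for (i in rev(seq_len(cfg$num_conv_blocks))) {
    p <- function(part) sprintf("trunk.conv%d.%s", i, part)
    cb <- cache$conv[[i]]
    if (!is.null(cb$pl)) {
      if (cfg$pool_type == "attention") {
        pb <- pool_attn_bwd(dh, cb$pl, P[[p("pool.w")]])
        addg(p("pool.w"), pb$dw)
        dh <- pb$dx
      } else {
        dh <- pool_max_bwd(dh, cb$pl)
      }
    }
    # dh is now gradient of h2 = cv2$y + cv$y
    cvb2 <- conv_bwd(dh, cb$cv2, P[[p("res.W")]])
    addg(p("res.W"), cvb2$dW); addg(p("res.b"), cvb2$db)
    dge2 <- gelu_bwd(cvb2$dx, cb$ge2)
    lnb2 <- layernorm_bwd(dge2, cb$ln2, P[[p("res.ln.g")]])
    addg(p("res.ln.g"), lnb2$dg); addg(p("res.ln.b"), lnb2$db)
    dcv <- dh + lnb2$dx
    cvb <- conv_bwd(dcv, cb$cv, P[[p("main.W")]])
    addg(p("main.W"), cvb$dW); addg(p("main.b"), cvb$db)
    if (i == 1L) {
      dh <- cvb$dx  # gradient wrt the one-hot input; unused
    } else {
      dge <- gelu_bwd(cvb$dx, cb$ge)
      lnb <- layernorm_bwd(dge, cb$ln, P[[p("ln.g")]])
      addg(p("ln.g"), lnb$dg); addg(p("ln.b"), lnb$db)
      dh <- lnb$dx
    }
  }
  G
}
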