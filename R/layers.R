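# Parameterised layer constructors.  Each returns a plain list of parameter
# tensors (class "dfn_tensor") plus metadata; forward helpers compose them on
# the autodiff tape.  Kernel weights use Kaiming fan-in initialisation drawn
# from the R RNG active at construction time.

kaiming_init <- function(k, cin_g, cout) {
  n <- k * k * cin_g * cout
  a <- array(stats::rnorm(n, 0, sqrt(2 / (k * k * cin_g))),
             c(k, k, cin_g, cout))
  a
}

new_conv <- function(k, cin, cout, groups = 1L) {
  if (cin %% groups != 0)
    stop("invalid configuration: groups (", groups,
         ") must divide input channels (", cin, ")")
  if (cout %% groups != 0)
    stop("invalid configuration: groups (", groups,
         ") must divide output channels (", cout, ")")
  list(w = t_param(kaiming_init(k, cin %/% groups, cout)),
       b = t_param(numeric(cout)),
       k = k, cin = cin, cout = cout, groups = as.integer(groups),
       pad = (k - 1L) %/% 2L)
}

conv_fw <- function(l, x) t_conv2d(x, l$w, l$b, l$pad, l$groups)

new_bn <- function(c) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(c)
  st$var <- rep(1, c)
  list(gamma = t_param(rep(1, c)), beta = t_param(numeric(c)), state = st)
}

# conv -> batch norm -> ReLU, the standard unit used by the encoder/decoder
# 3x3 stacks, the 7x7 global-dependency convolutions and every MBGM branch
new_cbr <- function(k, cin, cout, groups = 1L) {
  list(conv = new_conv(k, cin, cout, groups), bn = new_bn(cout))
}

cbr_fw <- function(l, x, training = FALSE) {
  t_relu(t_batchnorm(conv_fw(l$conv, x), l$bn$gamma, l$bn$beta,
                     l$bn$state, training))
}

# Parameter collection ---------------------------------------------------

# depth-first walk of a nested list structure collecting parameter tensors
# in a deterministic order (used by the optimiser, counters and checkpoints)
collect_params <- function(x, prefix = "") {
  if (is_tensor(x)) {
    if (x$requires_grad) {
      out <- list(x)
      names(out) <- prefix
      return(out)
    }
    return(list())
  }
  if (is.list(x)) {
    out <- list()
    nm <- names(x)
    for (i in seq_along(x)) {
      tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_params(x[[i]],
                                   if (nzchar(prefix)) paste0(prefix, ".", tag) else tag))
    }
    return(out)
  }
  list()
}

# collect batch-norm running-statistic environments (for checkpoints)
collect_bn_states <- function(x, prefix = "") {
  if (is_tensor(x)) return(list())
  if (is.environment(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nm <- names(x)
    for (i in seq_along(x)) {
      tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_bn_states(x[[i]],
                                      if (nzchar(prefix)) paste0(prefix, ".", tag) else tag))
    }
    return(out)
  }
  list()
}
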