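#' Floating-point operations of a convolution layer
#'
#' `FLOPS = 2 * H * W * (C_in * K^2 + 1) * C_out`, where `H x W` is the
#' feature map on which the kernel slides, `K` the kernel side, and
#' `C_in`/`C_out` the channel counts (the `+ 1` is the bias term, the
#' factor 2 counts multiply and add). Exact integer arithmetic (values are
#' doubles, exact below 2^53).
#'
#' @param H,W Feature-map height and width (positive integers).
#' @param K Kernel side.
#' @param C_in,C_out Input / output channel counts.
#' @return Operation count.
#' @examples
#' conv_flops(1, 1, 1, 1, 1) # 4
#' conv_flops(2, 2, 3, 3, 8) # 1792
#' @export
conv_flops <- function(H, W, K, C_in, C_out) {
  check_layer_spec(H, W, K, C_in, C_out)
  2 * H * W * (C_in * K^2 + 1) * C_out
}

#' Parameter count of a convolution layer
#'
#' `Params = C_in * K^2 * C_out`; independent of the feature-map size.
#'
#' @inheritParams conv_flops
#' @return Parameter count.
#' @examples
#' conv_params(1, 1, 1, 1, 1) # 1
#' conv_params(2, 2, 3, 3, 8) # 216
#' @export
conv_params <- function(H = 1, W = 1, K, C_in, C_out) {
  check_layer_spec(H, W, K, C_in, C_out)
  C_in * K^2 * C_out
}

check_layer_spec <- function(H, W, K, C_in, C_out) {
  vals <- c(H = H, W = W, K = K, C_in = C_in, C_out = C_out)
  bad <- vals <= 0 | vals != round(vals)
  if (any(bad)) {
    abort(paste("layer spec fields must be positive integers:",
                paste(names(vals)[bad], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Score a table of convolution layer specs
#'
#' @param layers Data frame with columns `H`, `W`, `K`, `C_in`, `C_out`.
#' @return The input with `flops` and `params` columns appended.
#' @examples
#' complexity_table(data.frame(H = 2, W = 2, K = 3, C_in = 3, C_out = 8))
#' @export
complexity_table <- function(layers) {
  l <- as_tibble(layers)
  mutate(l,
         flops = conv_flops(.data$H, .data$W, .data$K, .data$C_in, .data$C_out),
         params = conv_params(.data$H, .data$W, .data$K, .data$C_in,
                              .data$C_out))
}
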