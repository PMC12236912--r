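#' Architecture configuration for the 3D brain-age CNN
#'
#' Describes a scalable family of 3D convolutional regression networks. Each
#' block applies \code{convs_per_block} shape-preserving convolutions (kernel
#' 3, padding 1), each followed by batch normalization and a ReLU, and ends
#' with a stride-2 max pool that floor-halves every spatial dimension. After
#' the last block the activation is flattened and passed through a dropout /
#' fully-connected head ending in a single output unit with a terminal ReLU,
#' so predicted ages are non-negative by construction.
#'
#' The default is the full-size model: four input channels (gray matter,
#' white matter, T1, Jacobian) at 75 x 88 x 78 voxels, five blocks with
#' filters doubling 8 to 128, and a 128/32 fully-connected head - which has
#' exactly 1,020,721 trainable parameters.
#'
#' @param in_channels number of input channels.
#' @param input_dims integer triple of spatial input dimensions.
#' @param block_filters filter count per block; the number of blocks is
#'   \code{length(block_filters)}.
#' @param convs_per_block convolution + batch-norm pairs per block.
#' @param kernel isotropic convolution kernel size (odd).
#' @param padding zero padding per side; must keep convolutions
#'   shape-preserving (\code{padding == (kernel-1)/2}).
#' @param pool_stride max-pool stride (and window).
#' @param fc_widths widths of the hidden fully-connected layers.
#' @param output_width width of the output layer (1 for age regression).
#' @param dropout_rate dropout probability in the fully-connected head.
#' @return an object of class \code{arch_config}.
#' @export
arch_config <- function(in_channels = 4L,
                        input_dims = c(75L, 88L, 78L),
                        block_filters = c(8L, 16L, 32L, 64L, 128L),
                        convs_per_block = 2L,
                        kernel = 3L,
                        padding = 1L,
                        pool_stride = 2L,
                        fc_widths = c(128L, 32L),
                        output_width = 1L,
                        dropout_rate = 0.5) {
  if (in_channels < 1) stop_config("in_channels", "must be >= 1")
  if (length(input_dims) != 3 || any(input_dims < 1))
    stop_config("input_dims", "must be a positive voxel triple")
  if (length(block_filters) < 1 || any(block_filters < 1))
    stop_config("block_filters", "must be positive counts")
  if (convs_per_block < 1) stop_config("convs_per_block", "must be >= 1")
  if (kernel %% 2 != 1) stop_config("kernel", "must be odd")
  if (padding != (kernel - 1) / 2)
    stop_config("padding", "must equal (kernel-1)/2 (shape-preserving)")
  if (pool_stride != 2L)
    stop_config("pool_stride", "only stride-2 halving pools are supported")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate", "must be in [0, 1)")
  arch <- structure(list(
    in_channels = as.integer(in_channels),
    input_dims = as.integer(input_dims),
    block_filters = as.integer(block_filters),
    convs_per_block = as.integer(convs_per_block),
    kernel = as.integer(kernel),
    padding = as.integer(padding),
    pool_stride = as.integer(pool_stride),
    fc_widths = as.integer(fc_widths),
    output_width = as.integer(output_width),
    dropout_rate = dropout_rate
  ), class = "arch_config")
  sh <- forward_shapes(arch)  # validates that no dim collapses to 0
  if (sh$flatten_length < 1) stop_config("input_dims", "flatten length < 1")
  arch
}

#' Per-stage spatial dimensions and flatten length
#'
#' Convolutions are shape-preserving, so spatial dimensions change only at
#' the max-pool of each block, where every dimension d maps to floor(d/2).
#' The flatten length is the final filter count times the product of the
#' final spatial dimensions; for the full-size configuration this is
#' 128 x 2 x 2 x 2 = 1,024.
#'
#' @param arch an \code{arch_config}.
#' @return list with \code{stage_dims} (matrix, one row per stage starting at
#'   the input), \code{final_dims}, and \code{flatten_length}.
#' @export
forward_shapes <- function(arch) {
  stopifnot(inherits(arch, "arch_config"))
  d <- arch$input_dims
  stages <- matrix(d, nrow = 1)
  for (b in seq_along(arch$block_filters)) {
    d <- d %/% 2L
    if (any(d < 1))
      stop(sprintf("spatial dimension collapses to 0 at block %d", b),
           call. = FALSE)
    stages <- rbind(stages, d)
  }
  dimnames(stages) <- list(c("input", paste0("block", seq_along(arch$block_filters))),
                           c("X", "Y", "Z"))
  list(stage_dims = stages,
       final_dims = d,
       flatten_length = as.integer(prod(d) * utils::tail(arch$block_filters, 1)))
}

#' Closed-form count of trainable parameters
#'
#' Each convolution contributes k^3 * c_in * f weights plus f biases, each
#' batch-norm layer 2f (scale and shift), and each fully-connected layer
#' in * out weights plus out biases. Dropout and pooling contribute nothing.
#' For the default full-size configuration the count is 1,020,721.
#'
#' @param arch an \code{arch_config}.
#' @return integer parameter count.
#' @export
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "arch_config"))
  k3 <- arch$kernel^3
  total <- 0
  c_in <- arch$in_channels
  for (f in arch$block_filters) {
    for (j in seq_len(arch$convs_per_block)) {
      total <- total + k3 * c_in * f + f  # conv weights + biases
      total <- total + 2 * f              # batch-norm gamma + beta
      c_in <- f
    }
  }
  widths <- c(forward_shapes(arch)$flatten_length, arch$fc_widths,
              arch$output_width)
  for (i in seq_len(length(widths) - 1))
    total <- total + widths[i] * widths[i + 1] + widths[i + 1]
  as.integer(total)
}
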