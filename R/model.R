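#' Detector assembly from a layer table
#'
#' The network is described by a layer table in the same vocabulary as the
#' published per-layer parameter listing: one row per layer with its id,
#' source layer id(s) (`-1` = previous layer), the module registry name, the
#' argument vector, and the reference (printed) parameter count. The default
#' table shipped with the package is the MC-YOLOv13-L layout: a YOLO-style
#' backbone/neck in which C3k2 blocks carry a multi-scale linear attention
#' interior, a CMUNeXt block closes the backbone, cross-scale aggregation
#' feeds gated fusion tunnels, and an anchor-free head detects the four
#' drought grades at strides 8/16/32 of a 640-pixel input.
#'
#' @name detector
NULL

#' Read a layer table
#'
#' @param path CSV with columns `id`, `from` (semicolon-separated ids),
#'   `params` (reference parameter count), `module`, `args`. Defaults to the
#'   packaged MC-YOLOv13-L layout.
#' @return data frame of class `layer_table`.
#' @export
layer_table <- function(path = system.file("extdata", "mc_yolov13_l_layers.csv",
                                           package = "droughtvision")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "from", "params", "module", "args")
  if (!all(need %in% names(tab))) stop("layer table needs columns: ",
                                       paste(need, collapse = ", "))
  if (!identical(tab$id, seq_len(nrow(tab)) - 1L))
    stop("layer ids must be contiguous from 0")
  class(tab) <- c("layer_table", "data.frame")
  tab
}

#' Reference total parameter count of a layer table
#'
#' Sum of the table's printed per-layer `params` column (the column total of
#' the published layout equals its published network total).
#'
#' @param tab a [layer_table()].
#' @return integer sum.
#' @export
printed_total_parameters <- function(tab = layer_table()) {
  sum(as.numeric(tab$params))
}

parse_from <- function(s) as.integer(strsplit(as.character(s), ";")[[1L]])

parse_args <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  parts <- strsplit(s, ",")[[1L]]
  lapply(trimws(parts), function(p) {
    if (p %in% c("True", "False")) return(p == "True")
    if (p == "None") return(NULL)
    if (grepl("^\\[", p)) return(as.integer(strsplit(gsub("\\[|\\]", "", p), ";")[[1L]]))
    n <- suppressWarnings(as.numeric(p))
    if (!is.na(n)) n else p
  })
}

#' Instantiate one registry block from table-style arguments
#'
#' Registry names: `Conv`, `DSConv`, `C3k2_MSLA`, `A2C2f`, `CMUNeXt`,
#' `HyperACE`, `Upsample`, `DownsampleConv`, `FullPAD_Tunnel`, `Concat`,
#' `Detect`.
#'
#' @param module registry name.
#' @param args argument list as in the layer table (numeric vector or list).
#' @param ch_in channel count(s) of the incoming layer(s); needed by the
#'   multi-input blocks.
#' @return an `nn_module`.
#' @examples
#' count_parameters(build_block("Conv", list(128, 64, 1, 1)))  # 8320
#' @export
build_block <- function(module, args, ch_in = NULL) {
  a <- if (is.character(args)) parse_args(args) else as.list(args)
  num <- function(i, default = NULL) {
    if (length(a) >= i && !is.null(a[[i]])) a[[i]] else default
  }
  switch(module,
    Conv = nn_conv_block(num(1), num(2), num(3, 1L), num(4, 1L),
                         pad = num(5), groups = num(6, 1L)),
    DSConv = nn_dsconv(num(1), num(2), num(3, 3L), num(4, 1L)),
    C3k2_MSLA = nn_c3k2_msla(num(1), num(2), num(3, 1L), isTRUE(num(4, FALSE)),
                             e = num(5, 0.5)),
    A2C2f = nn_a2c2f(num(1), num(2), num(3, 1L)),
    CMUNeXt = nn_cmunext(num(1), depth = num(3, 1L)),
    HyperACE = nn_hyperace(ch_in, num(2)),
    Upsample = nn_upsample(num(2, 2L)),
    DownsampleConv = nn_downsample_conv(num(1)),
    FullPAD_Tunnel = nn_fullpad_tunnel(),
    Concat = nn_concat(),
    Detect = nn_detect(num(1), num(2)),
    stop("unknown module in registry: ", module))
}

block_out_channels <- function(module, args, ch_in) {
  a <- if (is.character(args)) parse_args(args) else as.list(args)
  switch(module,
    Conv = ,
    DSConv = ,
    C3k2_MSLA = ,
    A2C2f = ,
    CMUNeXt = a[[2L]],
    HyperACE = a[[2L]],
    Upsample = ch_in[1L],
    DownsampleConv = 2L * a[[1L]],
    FullPAD_Tunnel = ch_in[1L],
    Concat = sum(ch_in),
    Detect = NA_integer_,
    stop("unknown module: ", module))
}

#' Build a drought-stress detector from a layer table
#'
#' Instantiates every row of the table through the block registry and wires
#' the layers per the `from` column. The forward pass on a 640 x 640 input
#' emits three detection maps at strides 8, 16 and 32.
#'
#' @param tab a [layer_table()].
#' @param nc number of classes (4 drought grades).
#' @param input_side nominal input side in pixels.
#' @param seed seed for weight initialization.
#' @return object of class `drought_detector`.
#' @export
build_detector <- function(tab = layer_table(), nc = 4L, input_side = 640L,
                           seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(tab)
  layers <- vector("list", n)
  from <- vector("list", n)
  ch <- integer(n)
  for (i in seq_len(n)) {
    f <- parse_from(tab$from[i])
    f <- ifelse(f == -1L, i - 2L, f)     # -1 means previous layer (id i-2, 0-based)
    if (any(f >= i - 1L)) stop("wiring cycle: layer ", tab$id[i],
                               " consumes a later layer")
    from[[i]] <- f
    ch_in <- if (i == 1L) 3L else ch[f + 1L]
    layers[[i]] <- build_block(tab$module[i], tab$args[i], ch_in)
    ch[i] <- if (tab$module[i] == "Detect") NA_integer_
             else block_out_channels(tab$module[i], tab$args[i], ch_in)
  }
  # nothing consumes the gradient w.r.t. the input image
  if (!is.null(layers[[1L]]$children$conv))
    layers[[1L]]$children$conv$need_input_grad <- FALSE
  structure(list(layers = layers, from = from, channels = ch, table = tab,
                 nc = as.integer(nc), input_side = as.integer(input_side)),
            class = "drought_detector")
}

#' @export
print.drought_detector <- function(x, ...) {
  cat(sprintf("Drought-stress detector: %d layers, %s trainable parameters\n",
              length(x$layers), format(total_parameters(x), big.mark = ",")))
  cat(sprintf("  classes: %d; nominal input %d x %d; detect strides 8/16/32\n",
              x$nc, x$input_side, x$input_side))
  invisible(x)
}

#' Total trainable parameters of a built detector
#'
#' Sum of [count_parameters()] over all layers (parameter additivity).
#'
#' @param model a `drought_detector`.
#' @return integer count.
#' @export
total_parameters <- function(model) {
  sum(vapply(model$layers, count_parameters, integer(1)))
}

#' Forward pass through the detector
#'
#' @param model a `drought_detector`.
#' @param x input feature map `H x W x 3 x N` (grayscale images should be
#'   replicated to three channels), or a single `H x W` matrix.
#' @return list of per-scale raw output maps
#'   (`H/8, H/16, H/32`, each `h x w x (4+nc) x N`); layer outputs are cached
#'   on the model's layers for a subsequent backward pass.
#' @export
detector_forward <- function(model, x) {
  if (is.matrix(x)) {
    x <- array(rep(x, 3L), c(dim(x), 3L, 1L))
  }
  outs <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    f <- model$from[[i]]
    inp <- if (i == 1L) x else if (length(f) == 1L) outs[[f + 1L]]
           else lapply(f, function(j) outs[[j + 1L]])
    outs[[i]] <- model$layers[[i]]$forward(inp)
  }
  attr(outs[[length(outs)]], "strides") <-
    dim(x)[1L] / vapply(outs[[length(outs)]], function(o) dim(o)[1L], numeric(1))
  outs[[length(outs)]]
}

# Backward pass: dys is the gradient list for the detect outputs. Gradients
# accumulate into each module's $grads.
detector_backward <- function(model, dys, input_dims) {
  n <- length(model$layers)
  acc <- vector("list", n)          # gradient w.r.t. each layer's output
  acc_add <- function(slot, g) {
    if (is.null(acc[[slot]])) acc[[slot]] <<- g
    else acc[[slot]] <<- acc[[slot]] + g
  }
  # seed gradient at the detect layer
  dcur <- model$layers[[n]]$backward(dys)
  for (k in seq_along(model$from[[n]])) acc_add(model$from[[n]][k] + 1L, dcur[[k]])
  for (i in (n - 1L):1L) {
    if (is.null(acc[[i]])) next
    dx <- model$layers[[i]]$backward(acc[[i]])
    acc[[i]] <- NULL
    f <- model$from[[i]]
    if (i == 1L) return(invisible(dx))
    if (length(f) == 1L) acc_add(f + 1L, dx)
    else for (k in seq_along(f)) acc_add(f[k] + 1L, dx[[k]])
  }
  invisible(NULL)
}
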