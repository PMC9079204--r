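# Maximum activation maps: where in the image a trained network responds
# most strongly. The map of a layer for a given input is the channel-wise
# maximum of its post-activation feature maps, upsampled bilinearly to the
# input resolution and min-max rescaled to [0, 1].

#' Block-entry convolution layers
#'
#' Returns the first convolutional layer of each of the four convolution
#' blocks of a custom-family network, in order — the layers whose activation
#' maps are inspected. Selection is semantic (by registry name), not by raw
#' layer index.
#'
#' @param net A `scinti_network` of family `"linear"` or `"residual"`.
#' @return Character vector of four layer names.
#' @export
select_block_entry_layers <- function(net) {
  stopifnot(inherits(net, "scinti_network"))
  if (!net$family %in% c("linear", "residual"))
    stop("activation-map layer selection is only supported for the custom ",
         "families (linear, residual)")
  layers <- sprintf("block%d_conv1", 1:4)
  missing <- setdiff(layers, names(net$layers))
  if (length(missing) > 0)
    stop("network is missing block-entry layers: ",
         paste(missing, collapse = ", "))
  layers
}

#' Maximum activation map of a layer for one input
#'
#' Runs a forward pass, takes the channel-wise maximum of the layer's
#' post-activation feature maps at each spatial location, upsamples
#' bilinearly to the input resolution and min-max rescales to the unit interval
#' (a constant map rescales to all zeros).
#'
#' @param net A trained `scinti_network`.
#' @param layer Layer name (e.g. from [select_block_entry_layers()]).
#' @param image A normalized input matrix matching the network input size.
#' @return An `activation_map`: the map matrix with the source layer as an
#'   attribute.
#' @export
max_activation_map <- function(net, layer, image) {
  if (!layer %in% names(net$layers))
    stop("layer not in network: ", layer)
  fw <- nn_forward(net, image, training = FALSE, upto = layer)
  act <- fw$cache[[layer]]          # (h, w, C, 1)
  map <- apply(act[, , , 1, drop = FALSE], c(1, 2), max)
  size <- net$input_shape[1]
  if (!all(dim(map) == c(size, size)))
    map <- cg_resize_bilinear(map, size, size)
  rng <- range(map)
  map <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1])
         else matrix(0, size, size)
  structure(map, layer = layer, class = c("activation_map", class(map)))
}

#' Cardiac focus score of an activation map
#'
#' Mean map value inside a cardiac mask divided by the mean value outside;
#' values above 1 indicate that the network's strongest responses
#' concentrate on the cardiac region. A zero outside-mean (map supported
#' entirely on the mask) is reported as `cap`.
#'
#' @param map An [max_activation_map()] result (or any matrix).
#' @param cardiac_mask Logical matrix of the same shape; must be nonempty.
#' @param cap Value reported when the ratio diverges (default 100).
#' @return A single non-negative ratio.
#' @export
cardiac_focus_score <- function(map, cardiac_mask, cap = 100) {
  stopifnot(all(dim(map) == dim(cardiac_mask)))
  if (!any(cardiac_mask)) stop("empty cardiac mask")
  inside <- mean(map[cardiac_mask])
  outside <- mean(map[!cardiac_mask])
  if (outside == 0) {
    if (inside == 0) return(1)
    return(cap)
  }
  min(inside / outside, cap)
}

#' Write an activation-map montage
#'
#' Saves the input image next to the four block-entry activation maps as
#' 8-bit grayscale PNG panels (display only; raw matrices are returned
#' invisibly).
#'
#' @param net A trained custom-family network.
#' @param image Normalized input matrix.
#' @param path Output PNG path.
#' @return Invisibly, the list of four maps.
#' @export
write_activation_montage <- function(net, image, path) {
  layers <- select_block_entry_layers(net)
  maps <- lapply(layers, max_activation_map, net = net, image = image)
  to_unit <- function(m) {
    rng <- range(m)
    if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  panels <- c(list(to_unit(image)), lapply(maps, to_unit))
  gap <- matrix(1, nrow(image), 4)
  montage <- panels[[1]]
  for (p in panels[-1]) montage <- cbind(montage, gap, p)
  png::writePNG(montage, path)
  invisible(maps)
}
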