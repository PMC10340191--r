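# Analytic parameter and operation counting.
#
# Conventions (documented in the methods vignette): one multiply-
# accumulate is charged per kernel element and output position for
# convolutions (transposed convolutions likewise, per output position)
# and per weight for linear layers; routing affines of dynamic
# convolutions are charged per sample; normalization, activations and
# pooling are not charged. `flop_unit = "flop2"` doubles every count.

prof_row <- function(name, kind, params, macs) {
  tibble::tibble(name = name, kind = kind, params = params, macs = macs)
}

prof_conv <- function(name, l, in_side) {
  out <- if (l$transposed) in_side * l$stride else in_side %/% l$stride
  prof_row(name, if (l$transposed) "conv_transpose" else "conv",
           n_layer_params(l),
           as.numeric(l$k)^2 * l$ci * l$co * out^2)
}

prof_bn <- function(name, l) prof_row(name, "bn", n_layer_params(l), 0)

prof_condconv <- function(name, l, in_side, cfg, batch_macs_only = FALSE) {
  out <- in_side %/% l$stride
  conv_macs <- as.numeric(l$k)^2 * l$ci * l$co * out^2
  fac <- if (cfg$condconv_flops == "per_expert") l$n_experts else 1
  prof_row(name, "condconv", n_layer_params(l),
           fac * conv_macs + l$ci * l$n_experts)
}

prof_ca <- function(name, l, in_side) {
  prof_row(name, "coord_attention", n_layer_params(l),
           2 * l$c * l$cr * (2 * in_side) +  # shared + restoring 1x1 convs
             0)
}

prof_block <- function(name, l, in_side, cfg) {
  rows <- list()
  for (cn in c("conv1", "conv2")) {
    cl <- l[[cn]]
    rows[[length(rows) + 1]] <- if (cl$kind == "condconv") {
      prof_condconv(paste0(name, ".", cn), cl, in_side, cfg)
    } else {
      prof_conv(paste0(name, ".", cn), cl, in_side)
    }
  }
  rows[[length(rows) + 1]] <- prof_bn(paste0(name, ".bn1"), l$bn1)
  rows[[length(rows) + 1]] <- prof_bn(paste0(name, ".bn2"), l$bn2)
  if (!is.null(l$ca)) {
    rows[[length(rows) + 1]] <- prof_ca(paste0(name, ".ca"), l$ca, in_side)
  }
  dplyr::bind_rows(rows)
}

prof_bottleneck <- function(name, l, in_side) {
  rows <- list(
    prof_conv(paste0(name, ".conv1"), l$conv1, in_side),
    prof_conv(paste0(name, ".conv2"), l$conv2, in_side),
    prof_conv(paste0(name, ".conv3"), l$conv3, in_side),
    prof_bn(paste0(name, ".bn1"), l$bn1),
    prof_bn(paste0(name, ".bn2"), l$bn2),
    prof_bn(paste0(name, ".bn3"), l$bn3)
  )
  if (!is.null(l$proj)) {
    rows <- c(rows, list(prof_conv(paste0(name, ".proj"), l$proj, in_side),
                         prof_bn(paste0(name, ".proj_bn"), l$proj_bn)))
  }
  dplyr::bind_rows(rows)
}

prof_fusion <- function(name, l, sides) {
  rows <- list()
  for (j in seq_len(l$nb)) {
    for (k in seq_len(l$nb)) {
      if (j == k) next
      steps <- l$paths[[j]][[k]]
      side <- sides[j]
      for (i in seq_along(steps)) {
        nm <- sprintf("%s.%d_to_%d.%d", name, j, k, i)
        rows[[length(rows) + 1]] <- prof_conv(paste0(nm, ".conv"),
                                              steps[[i]]$conv, side)
        rows[[length(rows) + 1]] <- prof_bn(paste0(nm, ".bn"), steps[[i]]$bn)
        side <- if (steps[[i]]$conv$transposed) side * 2L else side %/% 2L
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-layer parameter and operation profile
#'
#' Walks the network in forward order, tracking spatial sizes from the
#' input side, and reports per-layer trainable parameter counts and
#' multiply-accumulate counts for one forward pass of a single image.
#'
#' @param network An `hrcc_network`.
#' @param input_size Square input side; defaults to the configured one.
#' @return A tibble with columns `name`, `kind`, `params`, `macs`.
#' @export
profile_network <- function(network, input_size = NULL) {
  cfg <- network$config
  if (is.null(input_size)) input_size <- cfg$input_size
  if (input_size %% 32 != 0) stop("input_size must be a multiple of 32",
                                  call. = FALSE)
  rows <- list()
  add <- function(x) rows[[length(rows) + 1]] <<- x

  add(prof_conv("stem.conv1", network$stem$conv1, input_size))
  add(prof_bn("stem.bn1", network$stem$bn1))
  add(prof_conv("stem.conv2", network$stem$conv2, input_size %/% 2L))
  add(prof_bn("stem.bn2", network$stem$bn2))

  sides <- (input_size %/% 4L) %/% c(1L, 2L, 4L, 8L)
  for (i in seq_along(network$stage1)) {
    add(prof_bottleneck(sprintf("stage1.unit%d", i), network$stage1[[i]],
                        sides[1]))
  }
  for (s in 2:4) {
    tr <- network$transitions[[s - 1]]
    add(prof_conv(sprintf("transition%d.conv", s), tr$conv, sides[s - 1]))
    add(prof_bn(sprintf("transition%d.bn", s), tr$bn))
    stage <- network$stages[[s - 1]]
    for (m in seq_along(stage$modules)) {
      for (b in seq_len(s)) {
        blocks <- stage$modules[[m]][[b]]
        for (i in seq_along(blocks)) {
          add(prof_block(sprintf("stage%d.mod%d.br%d.blk%d", s, m, b, i),
                         blocks[[i]], sides[b], cfg))
        }
      }
    }
    add(prof_fusion(sprintf("stage%d.fusion", s), stage$fusion, sides))
  }
  hd <- network$head
  for (k in 1:3) {
    st <- hd$steps[[k]]
    add(prof_conv(sprintf("head.step%d.down", k), st$down, sides[k]))
    add(prof_bn(sprintf("head.step%d.down_bn", k), st$down_bn))
    add(prof_conv(sprintf("head.step%d.fuse", k), st$fuse, sides[k + 1]))
    add(prof_bn(sprintf("head.step%d.fuse_bn", k), st$fuse_bn))
  }
  add(prof_conv("head.conv", hd$conv, sides[4]))
  add(prof_bn("head.conv_bn", hd$conv_bn))
  add(prof_row("head.fc1", "linear", n_layer_params(hd$fc1),
               as.numeric(hd$fc1$ci) * hd$fc1$co))
  add(prof_row("head.fc2", "linear", n_layer_params(hd$fc2),
               as.numeric(hd$fc2$ci) * hd$fc2$co))
  dplyr::bind_rows(rows)
}

#' Count trainable parameters
#'
#' Enumerates every trainable array in the network (kernels, expert
#' banks, routing affines, normalization scales/shifts, attention
#' transforms, linear layers) and sums their lengths.
#'
#' @param network An `hrcc_network`.
#' @return Integer-valued count of trainable scalars.
#' @export
count_parameters <- function(network) {
  sum(vapply(network_params(network), function(p) length(p$value), numeric(1)))
}

#' Count forward-pass operations
#'
#' Sums the per-layer multiply-accumulate counts from
#' [profile_network()] under the configuration's counting convention.
#'
#' @inheritParams profile_network
#' @param flop_unit Override the configured convention (`"mac"` or
#'   `"flop2"`).
#' @return Operation count for one image at the given input size.
#' @export
count_flops <- function(network, input_size = NULL, flop_unit = NULL) {
  unit <- flop_unit %||% network$config$flop_unit
  fac <- if (identical(unit, "flop2")) 2 else 1
  fac * sum(profile_network(network, input_size)$macs)
}

#' Full profile report
#'
#' @inheritParams profile_network
#' @return An `hrcc_profile_report`: a list with `total_params`,
#'   `total_flops`, `input_size`, `flop_unit` and the per-layer
#'   `breakdown` tibble.
#' @export
profile_report <- function(network, input_size = NULL) {
  cfg <- network$config
  if (is.null(input_size)) input_size <- cfg$input_size
  br <- profile_network(network, input_size)
  fac <- if (identical(cfg$flop_unit, "flop2")) 2 else 1
  structure(list(
    total_params = sum(br$params),
    total_flops = fac * sum(br$macs),
    input_size = input_size,
    flop_unit = cfg$flop_unit,
    breakdown = br
  ), class = "hrcc_profile_report")
}

#' @export
print.hrcc_profile_report <- function(x, ...) {
  cat("<hrcc_profile_report> input", x$input_size, "\n")
  cat(sprintf("  parameters: %.3f M\n", x$total_params / 1e6))
  cat(sprintf("  flops:      %.3f G (%s convention)\n",
              x$total_flops / 1e9, x$flop_unit))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
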