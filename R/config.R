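#' Network configuration
#'
#' Assembles and validates the set of hyperparameters that fully
#' determines a parallel multi-resolution network: four branch widths
#' (doubling from the high-resolution stream down), the number of
#' multi-scale attention modules per stage, blocks per module, the
#' dynamic-convolution expert count and placement, coordinate-attention
#' settings, and the classification head.
#'
#' @param branch_widths Integer vector of 4 channel widths, each twice
#'   the previous (high- to low-resolution stream).
#' @param modules_per_stage Integer vector of 3: modules in stages 2-4.
#' @param blocks_per_module Residual multi-scale blocks per module.
#' @param stage1_blocks Residual bottleneck units in stage 1.
#' @param stem_width Channels of the two stride-2 stem convolutions.
#' @param num_experts Expert kernels per dynamic convolution.
#' @param num_classes Number of independent output labels.
#' @param use_dynamic Replace block convolutions by dynamic convolutions?
#' @param dynamic_branches List of 3 integer vectors: for stages 2-4, the
#'   branch indices whose blocks use dynamic convolution (ignored when
#'   `use_dynamic` is `FALSE`).
#' @param use_attention Apply coordinate attention in each block?
#' @param ca_reduction Channel reduction of the shared attention transform.
#' @param head_hidden Two integers: width of the 1x1 head convolution and
#'   of the hidden linear layer.
#' @param input_size Expected square input side in pixels (must be a
#'   multiple of 32).
#' @param flop_unit Counting convention for the profiler: `"mac"` counts
#'   one operation per multiply-accumulate, `"flop2"` counts two.
#' @param condconv_flops `"per_expert"` charges each expert convolution;
#'   `"aggregated"` charges a single convolution with the mixed kernel
#'   plus the routing affine.
#'
#' @return An object of class `hrcc_config` (a validated list).
#' @seealso [hrcc_profile()] for the shipped named profiles.
#' @export
hrcc_config <- function(branch_widths = c(48L, 96L, 192L, 384L),
                        modules_per_stage = c(4L, 4L, 4L),
                        blocks_per_module = 4L,
                        stage1_blocks = 4L,
                        stem_width = 64L,
                        num_experts = 3L,
                        num_classes = 14L,
                        use_dynamic = TRUE,
                        dynamic_branches = list(1:2, 1:3, 1:4),
                        use_attention = TRUE,
                        ca_reduction = 32L,
                        head_hidden = c(2048L, 512L),
                        input_size = 224L,
                        flop_unit = c("mac", "flop2"),
                        condconv_flops = c("per_expert", "aggregated")) {
  cfg <- list(
    branch_widths = as.integer(branch_widths),
    modules_per_stage = as.integer(modules_per_stage),
    blocks_per_module = as.integer(blocks_per_module),
    stage1_blocks = as.integer(stage1_blocks),
    stem_width = as.integer(stem_width),
    num_experts = as.integer(num_experts),
    num_classes = as.integer(num_classes),
    use_dynamic = isTRUE(use_dynamic),
    dynamic_branches = lapply(dynamic_branches, as.integer),
    use_attention = isTRUE(use_attention),
    ca_reduction = as.integer(ca_reduction),
    head_hidden = as.integer(head_hidden),
    input_size = as.integer(input_size),
    flop_unit = match.arg(flop_unit),
    condconv_flops = match.arg(condconv_flops)
  )
  class(cfg) <- "hrcc_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid configuration field `%s`: %s", field, msg),
         call. = FALSE)
  }
  bw <- cfg$branch_widths
  if (length(bw) != 4 || any(bw < 1)) {
    fail("branch_widths", "must be 4 positive integers")
  }
  if (any(bw[-1] != 2L * bw[-4])) {
    fail("branch_widths", "must double from branch to branch")
  }
  if (length(cfg$modules_per_stage) != 3 || any(cfg$modules_per_stage < 1)) {
    fail("modules_per_stage", "must be 3 counts >= 1")
  }
  for (f in c("blocks_per_module", "stage1_blocks", "stem_width",
              "num_experts", "num_classes", "ca_reduction")) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      fail(f, "must be a single integer >= 1")
    }
  }
  if (length(cfg$head_hidden) != 2 || any(cfg$head_hidden < 1)) {
    fail("head_hidden", "must be 2 positive integers")
  }
  if (cfg$input_size < 32 || cfg$input_size %% 32 != 0) {
    fail("input_size", "must be a positive multiple of 32")
  }
  if (length(cfg$dynamic_branches) != 3) {
    fail("dynamic_branches", "must list branches for stages 2-4")
  }
  for (s in 1:3) {
    b <- cfg$dynamic_branches[[s]]
    if (length(b) && (any(b < 1) || any(b > s + 1))) {
      fail("dynamic_branches",
           sprintf("stage %d only has branches 1..%d", s + 1, s + 1))
    }
  }
  cfg
}

#' Named architecture profiles
#'
#' Three profiles are shipped. `"table1"` is the literal published
#' layout: widths 48/96/192/384, four modules of four blocks in every
#' stage, dynamic convolution and coordinate attention in every block.
#' `"calibrated"` is the profile whose analytic parameter and FLOP
#' budgets reproduce the published consumption figures (20.9/23.1/24.3 M
#' parameters and 9.71/10.87/11.25 G FLOPs at a 256 input); it uses
#' widths 41/82/164/328, a (4, 5, 1) module schedule with 2 blocks per
#' module, dynamic convolution on the three higher-resolution branches
#' of stage 4, and coordinate-attention reduction 2 (see the methods
#' vignette for the calibration). `"mini"` is a small configuration for
#' CPU experiments and tests.
#'
#' @param name One of `"table1"`, `"calibrated"`, `"mini"`.
#' @param ... Overrides passed on to [hrcc_config()].
#' @return An `hrcc_config`.
#' @export
hrcc_profile <- function(name = c("calibrated", "table1", "mini"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    table1 = list(),
    calibrated = list(
      branch_widths = c(41L, 82L, 164L, 328L),
      modules_per_stage = c(4L, 5L, 1L),
      blocks_per_module = 2L,
      dynamic_branches = list(integer(0), integer(0), 1:3),
      ca_reduction = 2L,
      input_size = 256L
    ),
    mini = list(
      branch_widths = c(8L, 16L, 32L, 64L),
      modules_per_stage = c(1L, 1L, 1L),
      blocks_per_module = 1L,
      stage1_blocks = 1L,
      stem_width = 16L,
      ca_reduction = 4L,
      head_hidden = c(64L, 32L),
      input_size = 32L
    )
  )
  args <- utils::modifyList(base, list(...))
  do.call(hrcc_config, args)
}

#' Read or write a configuration file
#'
#' The on-disk schema mirrors the arguments of [hrcc_config()]. YAML or
#' JSON is chosen by file extension. A `profile` key may name a shipped
#' profile to use as the base; remaining keys override it.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config()` returns an `hrcc_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  profile <- raw$profile
  raw$profile <- NULL
  if (!is.null(raw$dynamic_branches)) {
    raw$dynamic_branches <- lapply(raw$dynamic_branches, as.integer)
  }
  if (is.null(profile)) do.call(hrcc_config, raw)
  else do.call(hrcc_profile, c(list(name = profile), raw))
}

#' @param config An `hrcc_config` to serialize.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hrcc_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @export
print.hrcc_config <- function(x, ...) {
  cat("<hrcc_config>\n")
  cat("  branches:", paste(x$branch_widths, collapse = "/"),
      " modules:", paste(x$modules_per_stage, collapse = "/"),
      " blocks/module:", x$blocks_per_module, "\n")
  cat("  dynamic:", x$use_dynamic,
      " experts:", x$num_experts,
      " attention:", x$use_attention,
      " ca_reduction:", x$ca_reduction, "\n")
  cat("  classes:", x$num_classes, " input:", x$input_size, "\n")
  invisible(x)
}
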