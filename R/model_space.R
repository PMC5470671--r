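#' Canonical reciprocal connection pairs of the motor network
#'
#' The 9 reciprocal pairs over the five sources: SMA-cM1, SMA-iM1,
#' SMA-iPM, SMA-cPM, iPM-cPM, iPM-iM1, cPM-cM1, iPM-cM1, iM1-cM1.
#' Each pair contributes two directed edges, giving the 18-connection
#' full network.
#'
#' @return data frame `a`, `b` with 9 rows.
#' @export
motor_pairs <- function() {
  data.frame(
    a = c("SMA", "SMA", "SMA", "SMA", "iPM", "iPM", "cPM", "iPM", "iM1"),
    b = c("cM1", "iM1", "iPM", "cPM", "cPM", "iM1", "cM1", "cM1", "cM1"),
    stringsAsFactors = FALSE
  )
}

edge_ids <- function(edges) paste0(edges$from, "->", edges$to)

directed_edges <- function(pairs) {
  data.frame(from = c(pairs$a, pairs$b), to = c(pairs$b, pairs$a),
             stringsAsFactors = FALSE)[order(rep(seq_len(nrow(pairs)), 2)), ]
}

#' Define a coupling-model architecture
#'
#' A model is a set of directed edges over the five motor sources, a
#' per-edge flag saying whether the edge may carry cross-frequency
#' (nonlinear) coupling, a flag for cross-frequency terms in the
#' within-source (intrinsic) dynamics, and the set of sources receiving
#' the exogenous cue input.
#'
#' @param name identifier.
#' @param pairs data frame of reciprocal pairs (columns `a`, `b`); both
#'   directions are included. Must be a subset of [motor_pairs()].
#' @param nonlinear_edges logical: scalar recycled over edges, or one
#'   flag per directed edge.
#' @param intrinsic_nonlinear logical scalar.
#' @param input_targets character; sources receiving the cue input.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, pairs = motor_pairs(), nonlinear_edges = TRUE,
                       intrinsic_nonlinear = TRUE,
                       input_targets = default_source_set()$label) {
  all_pairs <- motor_pairs()
  key <- function(p) paste(pmin(p$a, p$b), pmax(p$a, p$b))
  if (!all(key(pairs) %in% key(all_pairs)))
    stop("pairs must be a subset of the 9 canonical reciprocal pairs")
  edges <- directed_edges(pairs)
  edges$nonlinear <- rep_len(nonlinear_edges, nrow(edges))
  sources <- default_source_set()$label
  if (!all(input_targets %in% sources)) stop("unknown input target")
  structure(list(name = name, edges = edges,
                 intrinsic_nonlinear = isTRUE(intrinsic_nonlinear),
                 input_targets = input_targets, sources = sources),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d directed edges (%d nonlinear), intrinsic %s\n",
              x$name, nrow(x$edges), sum(x$edges$nonlinear),
              if (x$intrinsic_nonlinear) "nonlinear" else "linear"))
  invisible(x)
}

#' Build the comparison model space
#'
#' Seven architectures spanning two hypothesis axes: where
#' cross-frequency (nonlinear) coupling is allowed (everywhere,
#' intrinsic connections only, extrinsic connections only) and whether
#' the edge set is the full 9-pair network or a reduced, more
#' lateralized 8-pair variant (dropping the iPM-cM1 diagonal pair).
#' DCM1 is the full nonlinear + linear model; the all-linear model has
#' the same edges as DCM1 with no cross-frequency terms anywhere. The
#' space is a convention, not a fixed truth: any list of [model_spec()]
#' objects can be passed downstream.
#'
#' @param source_set a [default_source_set()] (labels are taken from it).
#' @return named list of 7 `model_spec` objects: DCM1..DCM6, all_linear.
#' @export
build_model_space <- function(source_set = default_source_set()) {
  full <- motor_pairs()
  reduced <- full[!(full$a == "iPM" & full$b == "cM1"), ]
  list(
    DCM1 = model_spec("DCM1", full, TRUE, TRUE),
    DCM2 = model_spec("DCM2", full, FALSE, TRUE),
    DCM3 = model_spec("DCM3", full, TRUE, FALSE),
    DCM4 = model_spec("DCM4", reduced, TRUE, TRUE),
    DCM5 = model_spec("DCM5", reduced, FALSE, TRUE),
    DCM6 = model_spec("DCM6", reduced, TRUE, FALSE),
    all_linear = model_spec("all_linear", full, FALSE, FALSE)
  )
}
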