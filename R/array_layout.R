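#' Layout specification for a multi-subarray slide
#'
#' Defaults mirror an 8 x 60K slide: 8 subarrays of 62,976 features each,
#' 1,319 control features, and 20 replicate probes spotted 10 times each.
#'
#' @param subarrays number of subarrays per slide.
#' @param features_per_subarray features per subarray.
#' @param control_count control features per subarray.
#' @param replicate_probe_count number of biological probes used as technical
#'   replicates.
#' @param replicate_copies copies of each replicate probe.
#' @param seed integer seed for the placement permutation.
#' @param control_manifest data frame (control_id, class) with
#'   \code{control_count} rows; by default built by
#'   \code{\link{control_manifest}}.
#' @return object of class \code{layout_spec}.
#' @export
layout_spec <- function(subarrays = 8L, features_per_subarray = 62976L,
                        control_count = 1319L, replicate_probe_count = 20L,
                        replicate_copies = 10L, seed = 1L,
                        control_manifest = NULL) {
  if (is.null(control_manifest)) control_manifest <- carpoligo::control_manifest(control_count)
  stopifnot(nrow(control_manifest) == control_count,
            control_count + replicate_probe_count * replicate_copies <= features_per_subarray)
  structure(list(subarrays = as.integer(subarrays),
                 features_per_subarray = as.integer(features_per_subarray),
                 control_count = as.integer(control_count),
                 replicate_probe_count = as.integer(replicate_probe_count),
                 replicate_copies = as.integer(replicate_copies),
                 seed = as.integer(seed),
                 control_manifest = control_manifest),
            class = "layout_spec")
}

#' Default control manifest
#'
#' Splits a control budget into a 10-level spike-in series, stringency
#' probes, and corner markers. The default split of the 1,319-control budget
#' (1,000 spike-ins = 10 levels x 100 copies, 303 stringency, 16 corner) is
#' declared configuration: the commercial control grids publish the total,
#' not the composition.
#'
#' @param control_count total control features.
#' @param spike_levels number of spike-in concentration levels.
#' @param n_corner corner markers.
#' @param stringency_fraction fraction of the non-corner budget given to
#'   stringency probes (default 303/1303, the declared full-budget split).
#' @return data frame with columns \code{control_id}, \code{class}
#'   (\code{spikein}/\code{stringency}/\code{corner}) and, for spike-ins,
#'   \code{spike_level}.
#' @export
control_manifest <- function(control_count = 1319L, spike_levels = 10L,
                             n_corner = 16L, stringency_fraction = 303 / 1303) {
  stopifnot(control_count >= n_corner + spike_levels)
  n_str <- round((control_count - n_corner) * stringency_fraction)
  n_spike <- control_count - n_corner - n_str
  lev <- rep_len(seq_len(spike_levels), n_spike)
  lev <- sort(lev)
  df <- rbind(
    data.frame(control_id = sprintf("E1A_r60_L%02d_%03d", lev,
                                    stats::ave(lev, lev, FUN = seq_along)),
               class = "spikein", spike_level = lev),
    data.frame(control_id = sprintf("DCP_%03d", seq_len(n_str)),
               class = "stringency", spike_level = NA_integer_),
    data.frame(control_id = sprintf("CORNER_%02d", seq_len(n_corner)),
               class = "corner", spike_level = NA_integer_)
  )
  rownames(df) <- NULL
  df
}

#' Build a randomized array layout
#'
#' Fills each subarray with the control manifest, the replicate probes (the
#' first \code{replicate_probe_count} designed probes in probe_id order,
#' \code{replicate_copies} copies each) and biological probes: each unique
#' designed probe at least once when capacity allows, with residual capacity
#' filled by round-robin duplication. The position permutation is drawn from
#' a generator seeded with \code{spec$seed}; the same probes and seed give a
#' byte-identical layout.
#'
#' @param probes \code{probe_set} with at least one designed probe.
#' @param spec \code{layout_spec}.
#' @return object of class \code{array_layout}: data frame with columns
#'   \code{subarray}, \code{position} (1-based), \code{row}, \code{col},
#'   \code{feature_class} (\code{biological}/\code{replicate}/\code{spikein}/
#'   \code{stringency}/\code{corner}), \code{probe_id}; attribute
#'   \code{spec}.
#' @export
build_layout <- function(probes, spec = layout_spec()) {
  des <- probes[probes$status == "designed", , drop = FALSE]
  if (!nrow(des)) stop("no designed probes to place")
  n_feat <- spec$features_per_subarray
  n_ctrl <- spec$control_count
  n_rep_slots <- spec$replicate_probe_count * spec$replicate_copies
  n_bio <- n_feat - n_ctrl - n_rep_slots
  if (n_bio < 1L) stop("layout capacity violated: no room for biological probes")

  ids <- sort(des$probe_id)
  rep_ids <- ids[seq_len(min(spec$replicate_probe_count, length(ids)))]
  if (length(rep_ids) < spec$replicate_probe_count)
    stop("fewer designed probes than replicate_probe_count")
  bio_fill <- rep_len(ids, n_bio)  # round-robin duplication to fill capacity

  cm <- spec$control_manifest
  grid_w <- max(1L, floor(sqrt(n_feat)))
  set.seed(spec$seed)
  per_sub <- lapply(seq_len(spec$subarrays), function(sb) {
    feature_id <- c(cm$control_id,
                    rep(rep_ids, each = spec$replicate_copies),
                    bio_fill)
    feature_class <- c(as.character(cm$class),
                       rep("replicate", n_rep_slots),
                       rep("biological", n_bio))
    perm <- sample.int(n_feat)
    pos <- seq_len(n_feat)
    data.frame(subarray = sb, position = pos,
               row = (pos - 1L) %/% grid_w + 1L,
               col = (pos - 1L) %% grid_w + 1L,
               feature_class = feature_class[order(perm)],
               probe_id = feature_id[order(perm)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_sub)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("array_layout", "data.frame")
  out
}

#' @export
print.array_layout <- function(x, ...) {
  sp <- attr(x, "spec")
  cat("array_layout:", sp$subarrays, "subarray(s) x", sp$features_per_subarray,
      "features;", sum(x$feature_class == "biological") / sp$subarrays,
      "biological per subarray\n")
  invisible(x)
}

#' Export a layout design table
#'
#' @param layout \code{array_layout}
#' @param path output TSV path
#' @export
export_design_table <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[c("subarray", "row", "col",
                                             "feature_class", "probe_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design table written by \code{\link{export_design_table}}
#'
#' @param path TSV path
#' @return data frame with the exported columns.
#' @export
read_design_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
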