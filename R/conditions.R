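#' Structured error conditions
#'
#' All package errors are classed conditions so callers can catch a specific
#' failure mode (e.g. a malformed SMILES inside a batch) without string
#' matching. Every condition inherits from `mtqsar_error`.
#'
#' @param class character scalar, the condition subclass.
#' @param message human-readable message.
#' @param ... additional fields stored on the condition object.
#' @return Never returns; signals the condition.
#' @keywords internal
mtq_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mtqsar_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Condition subclasses used across the package:
#   malformed_smiles_error  unparsable SMILES (flagged, never fatal, in batch paths)
#   format_error            unreadable/unmappable tabular input
#   conflict_error          contradictory labels for one (compound, subclass) key
#   empty_class_error       a requested enzyme subclass has no records
#   degenerate_input_error  all-constant candidate features
#   degenerate_labels_error one-class label vector where two are required
#   length_mismatch_error   prediction/truth vectors of unequal length
#   unknown_descriptor_error name not in the descriptor registry
#   unknown_column_error    sort/filter on a column the table lacks
#   version_mismatch_error  model bundle schema/registry incompatibility
#   infeasible_config_error synthetic-data configuration cannot be realized
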