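# Internal helpers shared across modules.

GGM_ALPHABET <- c("A", "C", "G", "T", "N", "-")
GGM_ROLES <- c("Or", "On", "indica", "japonica")
GGM_CATEGORIES <- c("parental_diagnostic", "early_phase1", "lineage_indica",
                    "lineage_japonica", "transient_ambiguous", "recurrent_suspect")

# Classed errors so callers can distinguish configuration, alignment,
# alphabet, annotation, frame and estimation failures.
ggm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ggm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a reference_role given either a role tag ("Or") or a genome name.
resolve_role_name <- function(set, role_or_name) {
  if (role_or_name %in% names(set$roles)) return(role_or_name)
  hit <- names(set$roles)[set$roles == role_or_name]
  if (length(hit) == 0L) {
    ggm_stop(sprintf("reference role '%s' matches no genome in locus %s",
                     role_or_name, set$locus_id), "ggm_config_error")
  }
  hit[[1L]]
}

# Span utilities: 1-based inclusive [start, end] stored as 2-column matrices.
as_span_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  if (is.matrix(x)) {
    m <- x
  } else {
    m <- matrix(as.integer(unlist(x)), ncol = 2, byrow = TRUE)
  }
  colnames(m) <- c("start", "end")
  storage.mode(m) <- "integer"
  m
}

span_width <- function(m) if (nrow(m) == 0L) 0L else sum(m[, "end"] - m[, "start"] + 1L)

cols_in_spans <- function(m) {
  if (nrow(m) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(m)), function(i) seq.int(m[i, 1L], m[i, 2L])),
         use.names = FALSE)
}
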