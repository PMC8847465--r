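#' Construct a per-locus ortholog alignment with genealogical roles
#'
#' An `ortholog_set` holds one locus-region multiple alignment over the
#' four-taxon genealogy of Asian rice and its wild parents: one *O. rufipogon*
#' genome (role `"Or"`), one *O. nivara* genome (role `"On"`), one to three
#' indica genomes (role `"indica"`) and one japonica genome (role
#' `"japonica"`). An optional extra genome (role `"extra"`) may ride along for
#' concordance checks; it never participates in mutation calling.
#'
#' @param seqs Named character vector of aligned sequences (equal length,
#'   alphabet `A,C,G,T,N,-`; case-insensitive).
#' @param roles Named character vector mapping each sequence name to its role.
#' @param locus_id Locus identifier.
#' @param region_kind `"five_prime"` or `"coding_genomic"`.
#' @return An object of class `ortholog_set` with elements `locus_id`,
#'   `region_kind`, `mat` (character matrix, one row per genome), `roles` and
#'   `alignment_length`.
#' @export
ortholog_set <- function(seqs, roles,
                         locus_id = "locus",
                         region_kind = c("five_prime", "coding_genomic")) {
  region_kind <- match.arg(region_kind)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    ggm_stop("sequences must have unique names", "ggm_config_error")
  }
  missing_roles <- setdiff(names(seqs), names(roles))
  if (length(missing_roles) > 0L) {
    ggm_stop(paste0("no role assigned for genome(s): ",
                    paste(missing_roles, collapse = ", ")), "ggm_config_error")
  }
  roles <- roles[names(seqs)]
  bad <- setdiff(unique(roles), c(GGM_ROLES, "extra"))
  if (length(bad) > 0L) {
    ggm_stop(paste0("unknown role(s): ", paste(bad, collapse = ", ")),
             "ggm_config_error")
  }
  n_by_role <- table(factor(roles, levels = c(GGM_ROLES, "extra")))
  if (n_by_role[["Or"]] != 1L || n_by_role[["On"]] != 1L ||
      n_by_role[["japonica"]] != 1L) {
    ggm_stop("exactly one Or, one On and one japonica genome are required",
             "ggm_config_error")
  }
  if (n_by_role[["indica"]] < 1L || n_by_role[["indica"]] > 3L) {
    ggm_stop("between 1 and 3 indica genomes are required", "ggm_config_error")
  }
  if (n_by_role[["extra"]] > 1L) {
    ggm_stop("at most one extra genome is allowed", "ggm_config_error")
  }

  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    ggm_stop(sprintf("alignment lengths differ at locus %s: %s", locus_id,
                     paste(lens, collapse = ", ")), "ggm_alignment_error")
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  illegal <- setdiff(unique(as.vector(mat)), GGM_ALPHABET)
  if (length(illegal) > 0L) {
    ggm_stop(paste0("illegal character(s) in alignment: ",
                    paste(illegal, collapse = ", ")), "ggm_alphabet_error")
  }
  structure(
    list(locus_id = locus_id, region_kind = region_kind, mat = mat,
         roles = roles, alignment_length = ncol(mat)),
    class = "ortholog_set"
  )
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> locus %s, region %s: %d genomes x %d columns\n",
              x$locus_id, x$region_kind, nrow(x$mat), x$alignment_length))
  cat("  roles:", paste(sprintf("%s=%s", names(x$roles), x$roles),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Read a per-locus ortholog alignment from FASTA
#'
#' @param fasta_path Path to an aligned multi-FASTA.
#' @param role_map Named character vector mapping record names to roles
#'   (`"Or"`, `"On"`, `"indica"`, `"japonica"`, optionally `"extra"`).
#' @param region_kind `"five_prime"` or `"coding_genomic"`.
#' @param locus_id Locus identifier; defaults to the file stem.
#' @return A validated [ortholog_set()].
#' @export
load_ortholog_set <- function(fasta_path, role_map,
                              region_kind = c("five_prime", "coding_genomic"),
                              locus_id = NULL) {
  region_kind <- match.arg(region_kind)
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- as.character(ss)
  ortholog_set(seqs, role_map,
               locus_id = locus_id %||%
                 sub("\\.[^.]*$", "", basename(fasta_path)),
               region_kind = region_kind)
}

#' Write an ortholog set back to FASTA
#' @param set An [ortholog_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_set <- function(set, path) {
  seqs <- apply(set$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# Rows of set$mat belonging to a role, in input order.
role_rows <- function(set, role) which(set$roles == role)

#' Collapse indica genomes to a consensus sequence
#'
#' Column-wise rule: if the (first two) indica genomes agree, their shared
#' state is the consensus; a third, lower-coverage genome is consulted only to
#' break a tie between the first two. Columns that remain unresolved are
#' flagged ambiguous and excluded from fixed-mutation calling downstream
#' (reported as transient).
#'
#' @param set An [ortholog_set()].
#' @return List with `state` (character vector, `NA` where ambiguous),
#'   `ambiguous` and `tie_broken` (logical vectors over alignment columns).
#' @export
consensus_indica <- function(set) {
  idx <- role_rows(set, "indica")
  L <- set$alignment_length
  if (length(idx) == 1L) {
    return(list(state = set$mat[idx, ], ambiguous = rep(FALSE, L),
                tie_broken = rep(FALSE, L)))
  }
  g1 <- set$mat[idx[1L], ]
  g2 <- set$mat[idx[2L], ]
  state <- g1
  agree <- g1 == g2
  ambiguous <- !agree
  tie_broken <- rep(FALSE, L)
  if (length(idx) >= 3L && any(!agree)) {
    g3 <- set$mat[idx[3L], ]
    fix1 <- !agree & g3 == g1
    fix2 <- !agree & g3 == g2
    state[fix2] <- g2[fix2]
    resolved <- fix1 | fix2
    tie_broken[resolved] <- TRUE
    ambiguous <- !agree & !resolved
  }
  state[ambiguous] <- NA_character_
  list(state = state, ambiguous = ambiguous, tie_broken = tie_broken)
}

# Four-role state matrix (rows Or, On, I, J) over alignment columns.
# I is the indica consensus; NA where the consensus is ambiguous.
role_state_matrix <- function(set, cons = consensus_indica(set)) {
  rbind(Or = set$mat[role_rows(set, "Or"), ],
        On = set$mat[role_rows(set, "On"), ],
        I = cons$state,
        J = set$mat[role_rows(set, "japonica"), ])
}

# Ungapped length of one genome (by role or name) within optional spans.
ungapped_length <- function(set, role_or_name, spans = NULL) {
  nm <- resolve_role_name(set, role_or_name)
  v <- set$mat[nm, ]
  if (!is.null(spans)) v <- v[cols_in_spans(as_span_matrix(spans))]
  sum(v != "-")
}
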