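## Alignment filters applied before rate estimation. Filter order is fixed:
## first-intron drop -> exon-flank trim -> ambiguous-column mask -> CpG
## removal -> gene-level length floor. Every filter reports exactly how many
## columns it removed, so input columns = retained + removed (site ledger).

#' Intron alignment sets
#'
#' A container for per-gene pairwise intronic alignments, ordered by intron
#' position, with a chromosome class label (`"X"`, `"Y"` or `"A"`).
#'
#' @param gene gene label.
#' @param class chromosome class: `"X"`, `"Y"` or `"A"`.
#' @param introns list of character matrices (2 rows = the two species,
#'   columns = aligned positions), in positional order.
#' @return object of class `intron_gene`.
#' @export
intron_gene <- function(gene, class = c("A", "X", "Y"), introns) {
  class <- match.arg(class)
  stopifnot(length(introns) >= 1, all(vapply(introns, is.matrix, TRUE)))
  structure(list(gene = gene, class = class, introns = introns),
            class = "intron_gene")
}

#' @rdname intron_gene
#' @param genes list of `intron_gene`.
#' @export
intron_set <- function(genes) {
  stopifnot(all(vapply(genes, inherits, TRUE, "intron_gene")))
  structure(list(genes = genes), class = "intron_set")
}

#' @export
print.intron_set <- function(x, ...) {
  cls <- vapply(x$genes, function(g) g$class, "")
  cat("Intron alignment set:", length(x$genes), "genes (",
      paste(names(table(cls)), table(cls), collapse = ", "), ")\n")
  invisible(x)
}

#' Remove columns with gaps or ambiguity
#'
#' Drops every column containing a symbol other than A, C, G, T in any
#' sequence. The number of removed columns is attached as attribute
#' `n_removed`.
#'
#' @param aln character matrix (sequences x columns).
#' @return filtered matrix.
#' @export
mask_ambiguous_columns <- function(aln) {
  clean <- colSums(matrix(toupper(aln) %in% BASES, nrow = nrow(aln))) == nrow(aln)
  out <- aln[, clean, drop = FALSE]
  attr(out, "n_removed") <- sum(!clean)
  out
}

#' Remove detectable CpG sites
#'
#' Removes every column participating in a C followed by a G in any sequence.
#' Adjacency is assessed on the clean columns only (columns that are pure
#' A/C/G/T in all sequences), so the result does not depend on whether the
#' ambiguity mask runs before or after this filter, and removal is iterated
#' to a fixpoint so the filter is idempotent (removing a CG pair can bring a
#' new C next to a G).
#'
#' @param aln character matrix (sequences x columns).
#' @return filtered matrix with attribute `n_removed`.
#' @export
remove_cpg <- function(aln) {
  up <- toupper(aln)
  clean_idx <- which(colSums(matrix(up %in% BASES, nrow = nrow(aln))) == nrow(aln))
  drop <- logical(ncol(aln))
  repeat {
    active <- clean_idx[!drop[clean_idx]]
    if (length(active) < 2) break
    sub <- up[, active, drop = FALSE]
    mark <- logical(length(active))
    for (r in seq_len(nrow(sub))) {
      hit <- which(sub[r, -length(active)] == "C" & sub[r, -1] == "G")
      if (length(hit)) mark[c(hit, hit + 1)] <- TRUE
    }
    if (!any(mark)) break
    drop[active[mark]] <- TRUE
  }
  out <- aln[, !drop, drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Apply the full intron filtering cascade
#'
#' Per gene: the first intron is dropped (regulatory content), `flank`
#' columns are trimmed from both ends of every remaining intron (splice
#' sites and enhancers), introns shorter than `min_intron` columns after
#' trimming are dropped, ambiguous columns and CpG sites are removed, and
#' genes whose total retained alignment is not strictly greater than
#' `min_total` columns are dropped entirely. A per-gene audit ledger is
#' attached as attribute `audit`; its removal counts plus `columns_out` sum
#' exactly to `columns_in`.
#'
#' @param gene_set an [intron_set()].
#' @param min_total gene-level floor on total retained columns (strict `>`).
#' @param flank columns trimmed at each intron end.
#' @param min_intron minimum intron columns after trimming.
#' @return filtered [intron_set()] with attribute `audit` (data.frame).
#' @export
filter_introns <- function(gene_set, min_total = 1000, flank = 20,
                           min_intron = 40) {
  audits <- list()
  kept <- list()
  for (g in gene_set$genes) {
    a <- list(gene = g$gene, class = g$class,
              columns_in = sum(vapply(g$introns, ncol, 0L)),
              removed_first_intron = 0L, removed_flank = 0L,
              removed_short_intron = 0L, removed_ambiguous = 0L,
              removed_cpg = 0L, columns_out = 0L, retained = FALSE)
    introns <- g$introns
    a$removed_first_intron <- ncol(introns[[1]])
    introns <- introns[-1]
    out <- list()
    for (intr in introns) {
      w <- ncol(intr)
      trim <- min(2L * flank, w)
      a$removed_flank <- a$removed_flank + trim
      if (w - trim <= 0) next
      intr <- intr[, seq(flank + 1L, w - flank), drop = FALSE]
      if (ncol(intr) < min_intron) {
        a$removed_short_intron <- a$removed_short_intron + ncol(intr)
        next
      }
      intr <- mask_ambiguous_columns(intr)
      a$removed_ambiguous <- a$removed_ambiguous + attr(intr, "n_removed")
      intr <- remove_cpg(intr)
      a$removed_cpg <- a$removed_cpg + attr(intr, "n_removed")
      if (ncol(intr) > 0) out[[length(out) + 1L]] <- intr
    }
    a$columns_out <- sum(vapply(out, ncol, 0L))
    a$retained <- length(out) > 0 && a$columns_out > min_total
    audits[[length(audits) + 1L]] <- as.data.frame(a, stringsAsFactors = FALSE)
    if (a$retained)
      kept[[length(kept) + 1L]] <- intron_gene(g$gene, g$class, out)
  }
  res <- intron_set(kept)
  attr(res, "audit") <- do.call(rbind, audits)
  res
}

#' Pool the introns of an intron set, optionally restricted to one class
#'
#' @param gene_set an [intron_set()].
#' @param class optional chromosome class filter.
#' @return flat list of pairwise intron alignments.
#' @export
pool_introns <- function(gene_set, class = NULL) {
  genes <- gene_set$genes
  if (!is.null(class)) genes <- Filter(function(g) g$class == class, genes)
  unlist(lapply(genes, function(g) g$introns), recursive = FALSE)
}
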