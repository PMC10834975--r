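#' Transcription/expression (T/E) profiles per mature miRNA
#'
#' Combines sequencing-based detection (E) with gene-level promoter-reporter
#' transcription calls (T) lifted to mature arms through the annotation.
#' Mature miRNAs whose gene has no transcription record are excluded with a
#' warning (the analysable set — miRNAs with an interpretable promoter —
#' can also be given explicitly).
#'
#' @param detection \code{DetectionTable} over the somatic tissues.
#' @param tmap \code{TranscriptionMap} (gene x tissue x age).
#' @param annotation Data frame mapping \code{mature_id} to \code{gene_id}.
#' @param analysable Optional character vector of mature ids to restrict to.
#' @param tissues Tissues to analyse; defaults to the tissues shared by
#'   detection and the transcription map.
#' @return List of logical arrays \code{E} and \code{T_} (mature x tissue x
#'   age) over the analysable matures, plus \code{tissues}, \code{ages},
#'   \code{annotation}.
#' @export
te_profiles <- function(detection, tmap, annotation, analysable = NULL,
                        tissues = NULL) {
  stopifnot(inherits(detection, "DetectionTable"), inherits(tmap, "TranscriptionMap"))
  det_dims <- dimnames(detection$per_group)
  if (is.null(tissues)) tissues <- intersect(det_dims[[2]], dimnames(tmap$calls)[[2]])
  ages <- intersect(det_dims[[3]], dimnames(tmap$calls)[[3]])
  if (length(tissues) < 2) stop("need at least two shared tissues between E and T")
  matures <- intersect(det_dims[[1]], annotation$mature_id)
  gene_of <- setNames(annotation$gene_id, annotation$mature_id)
  no_t <- matures[!(gene_of[matures] %in% dimnames(tmap$calls)[[1]])]
  if (length(no_t) > 0) {
    warning(length(no_t), " mature miRNA(s) lack a transcription record and were excluded: ",
            paste(head(no_t, 5), collapse = ", "),
            if (length(no_t) > 5) ", ...")
    matures <- setdiff(matures, no_t)
  }
  if (!is.null(analysable)) matures <- intersect(matures, analysable)
  E <- detection$per_group[matures, tissues, ages, drop = FALSE]
  E[is.na(E)] <- FALSE
  T_ <- tmap$calls[gene_of[matures], tissues, ages, drop = FALSE]
  dimnames(T_)[[1]] <- matures
  list(E = E, T_ = T_, tissues = tissues, ages = ages,
       annotation = annotation[annotation$mature_id %in% matures, , drop = FALSE])
}

#' Classify potentially inter-tissue transported miRNAs (PITT-miRs)
#'
#' A mature miRNA is PITT in (tissue, age) when it is detected by
#' sequencing there without a transcription call: E and not T. The global
#' PITT set collects miRNAs that are PITT in at least one tissue-age.
#'
#' @param profiles Output of \code{\link{te_profiles}}.
#' @return List with \code{pitt} (character set), \code{table} (long data
#'   frame mature_id, tissue, age, expressed, transcribed, pitt).
#' @export
classify_pitt <- function(profiles) {
  d <- dimnames(profiles$E)
  long <- expand.grid(mature_id = d[[1]], tissue = d[[2]], age = d[[3]],
                      stringsAsFactors = FALSE)
  long$expressed <- as.vector(profiles$E)
  long$transcribed <- as.vector(profiles$T_)
  long$pitt <- long$expressed & !long$transcribed
  pitt <- sort(unique(long$mature_id[long$pitt]))
  list(pitt = pitt, table = long)
}

#' Build the directed inter-tissue trafficking network
#'
#' For each mature miRNA at the given age, source tissues S are those with
#' both expression and transcription (E and T) and receiver tissues R those
#' with expression only (E and not T). The miRNA joins every directed edge
#' S x R; a miRNA with receivers but no internal source is attributed to an
#' "Other" source node (transported in from outside the profiled tissues).
#' Every ordered tissue pair (plus Other -> tissue) is represented so that
#' zero-weight edges still receive a permutation null.
#'
#' @param profiles Output of \code{\link{te_profiles}}.
#' @param age Age label, e.g. "D1".
#' @return A \code{TraffickingNetwork}: \code{edges} data frame (source,
#'   target, weight, mirnas), \code{membership} per-miRNA source/receiver
#'   sets, \code{tissues}, \code{age}.
#' @export
build_trafficking_network <- function(profiles, age) {
  stopifnot(age %in% dimnames(profiles$E)[[3]])
  tissues <- profiles$tissues
  E <- profiles$E[, , age, drop = TRUE]
  T_ <- profiles$T_[, , age, drop = TRUE]
  if (is.null(dim(E))) {  # single mature
    E <- matrix(E, nrow = 1, dimnames = list(dimnames(profiles$E)[[1]], tissues))
    T_ <- matrix(T_, nrow = 1, dimnames = list(dimnames(profiles$T_)[[1]], tissues))
  }
  membership <- lapply(rownames(E), function(m) {
    S <- tissues[E[m, ] & T_[m, ]]
    R <- tissues[E[m, ] & !T_[m, ]]
    list(mature_id = m, sources = S, receivers = R,
         other_source = length(S) == 0 && length(R) > 0)
  })
  names(membership) <- rownames(E)
  edges <- expand.grid(source = c(tissues, "Other"), target = tissues,
                       stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  rownames(edges) <- NULL
  edge_mirnas <- vector("list", nrow(edges))
  key <- paste(edges$source, edges$target, sep = "->")
  idx <- setNames(seq_along(key), key)
  for (mb in membership) {
    if (length(mb$receivers) == 0) next
    src <- if (mb$other_source) "Other" else mb$sources
    for (s in src) for (r in mb$receivers) {
      k <- idx[[paste(s, r, sep = "->")]]
      edge_mirnas[[k]] <- c(edge_mirnas[[k]], mb$mature_id)
    }
  }
  edges$weight <- vapply(edge_mirnas, length, integer(1))
  edges$mirnas <- vapply(edge_mirnas, paste, character(1), collapse = ";")
  structure(list(edges = edges, membership = membership,
                 tissues = tissues, age = age),
            class = "TraffickingNetwork")
}

#' @export
print.TraffickingNetwork <- function(x, ...) {
  cat(sprintf("TraffickingNetwork (%s): %d tissues (+Other), total flow %d\n",
              x$age, length(x$tissues), sum(x$edges$weight)))
  invisible(x)
}

#' Per-replicate source/receiver flow counts
#'
#' Re-derives the trafficking roles tissue by tissue using per-replicate
#' expression calls (count > threshold in that single sample), so that each
#' replicate yields its own network. For every tissue, age and replicate:
#' out = number of distinct miRNAs with the tissue among their sources and
#' a non-empty receiver set; in = number of distinct miRNAs received there.
#'
#' @param x \code{ExpressionMatrix} of raw counts over the somatic tissues.
#' @param tmap \code{TranscriptionMap}.
#' @param annotation Mature-to-gene annotation.
#' @param threshold Per-replicate read threshold (strict). Default 5.
#' @param analysable Optional restriction of the mature set.
#' @return Tidy data frame: tissue, age, replicate, n_out, n_in.
#' @export
flow_summary <- function(x, tmap, annotation, threshold = 5, analysable = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(tmap, "TranscriptionMap"))
  tissues <- intersect(unique(x$samples$tissue), dimnames(tmap$calls)[[2]])
  ages <- intersect(unique(x$samples$age), dimnames(tmap$calls)[[3]])
  gene_of <- setNames(annotation$gene_id, annotation$mature_id)
  matures <- intersect(rownames(x$values), annotation$mature_id)
  matures <- matures[gene_of[matures] %in% dimnames(tmap$calls)[[1]]]
  if (!is.null(analysable)) matures <- intersect(matures, analysable)
  reps <- sort(unique(x$samples$replicate))
  rows <- list()
  for (a in ages) {
    for (r in reps) {
      E <- matrix(FALSE, length(matures), length(tissues),
                  dimnames = list(matures, tissues))
      for (t in tissues) {
        j <- which(x$samples$tissue == t & x$samples$age == a & x$samples$replicate == r)
        if (length(j) == 1) E[, t] <- x$values[matures, j] > threshold
      }
      T_ <- tmap$calls[gene_of[matures], tissues, a, drop = FALSE][, , 1]
      if (is.null(dim(T_))) T_ <- matrix(T_, nrow = length(matures),
                                         dimnames = list(matures, tissues))
      S <- E & T_
      R <- E & !T_
      has_receiver <- rowSums(R) > 0
      for (t in tissues) {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = t, age = a, replicate = r,
          n_out = sum(S[, t] & has_receiver),
          n_in = sum(R[, t]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
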