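DESIGN_COLUMNS <- c("probe_id", "probeset_id", "group", "role", "event_id",
                    "event_type", "gene_id", "chrom", "start", "end", "strand")

EVENT_TYPES   <- c("cassette", "alt5", "alt3", "mutually_exclusive")
PROBESET_GROUPS <- c("inclusion", "exclusion", "constitutive")
PROBESET_ROLES  <- c("exon_body", "junction")

#' Array design: the probe/probeset/event/gene hierarchy
#'
#' An \code{ArrayDesign} describes a junction-array layout: probes grouped
#' into probesets, probesets attached either to an alternative-splicing
#' event (as \emph{inclusion} or \emph{exclusion} evidence) or marked
#' \emph{constitutive} (event_id \code{"."}), and events attached to genes.
#' It is the coordinate system over which every statistic in the pipeline
#' is aggregated.
#'
#' @param table data.frame with columns \code{probe_id}, \code{probeset_id},
#'   \code{group} (inclusion/exclusion/constitutive), \code{role}
#'   (exon_body/junction), \code{event_id} (\code{"."} for constitutive
#'   probesets), \code{event_type} (cassette, alt5, alt3,
#'   mutually_exclusive, or \code{"."}), \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive), \code{strand}
#'   (\code{"+"}/\code{"-"}), one row per probe.
#' @return An object of class \code{ArrayDesign}: a list with the validated
#'   probe-level \code{table} plus derived \code{probes}, \code{probesets},
#'   \code{events} and \code{genes} data.frames.
#' @export
ArrayDesign <- function(table) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(DESIGN_COLUMNS, names(table))
  if (length(missing_cols))
    stop("design table missing columns: ", paste(missing_cols, collapse = ", "))
  table <- table[DESIGN_COLUMNS]
  for (col in c("probe_id", "probeset_id", "group", "role", "event_id",
                "event_type", "gene_id", "chrom", "strand"))
    table[[col]] <- as.character(table[[col]])
  table$start <- as.integer(table$start)
  table$end   <- as.integer(table$end)
  rownames(table) <- NULL
  validate_design_table(table)

  probes <- data.frame(probe_id = table$probe_id,
                       probeset_id = table$probeset_id,
                       stringsAsFactors = FALSE)
  ps_first <- !duplicated(table$probeset_id)
  probesets <- data.frame(probeset_id = table$probeset_id[ps_first],
                          event_id = table$event_id[ps_first],
                          group = table$group[ps_first],
                          role = table$role[ps_first],
                          gene_id = table$gene_id[ps_first],
                          stringsAsFactors = FALSE)
  ev_rows <- table$event_id != "."
  ev_first <- ev_rows & !duplicated(table$event_id)
  events <- data.frame(event_id = table$event_id[ev_first],
                       gene_id = table$gene_id[ev_first],
                       event_type = table$event_type[ev_first],
                       chrom = table$chrom[ev_first],
                       start = table$start[ev_first],
                       end = table$end[ev_first],
                       strand = table$strand[ev_first],
                       stringsAsFactors = FALSE)
  g_first <- !duplicated(table$gene_id)
  genes <- data.frame(gene_id = table$gene_id[g_first],
                      chrom = table$chrom[g_first],
                      strand = table$strand[g_first],
                      start = as.integer(tapply(table$start, table$gene_id, min)[table$gene_id[g_first]]),
                      end = as.integer(tapply(table$end, table$gene_id, max)[table$gene_id[g_first]]),
                      stringsAsFactors = FALSE)
  rownames(events) <- rownames(genes) <- rownames(probesets) <- NULL
  structure(list(table = table, probes = probes, probesets = probesets,
                 events = events, genes = genes),
            class = "ArrayDesign")
}

# Invariant checks shared by the reader and the generator.
validate_design_table <- function(tab) {
  if (nrow(tab) == 0L) stop("no probes in design")
  dup <- tab$probe_id[duplicated(tab$probe_id)]
  if (length(dup))
    stop("duplicate probe_id in design: ", paste(unique(dup), collapse = ", "))
  bad_group <- setdiff(unique(tab$group), PROBESET_GROUPS)
  if (length(bad_group))
    stop("unknown probeset group: ", paste(bad_group, collapse = ", "))
  bad_role <- setdiff(unique(tab$role), PROBESET_ROLES)
  if (length(bad_role))
    stop("unknown probeset role: ", paste(bad_role, collapse = ", "))
  bad_type <- setdiff(unique(tab$event_type), c(EVENT_TYPES, "."))
  if (length(bad_type))
    stop("unknown event_type: ", paste(bad_type, collapse = ", "))
  bad_strand <- setdiff(unique(tab$strand), c("+", "-"))
  if (length(bad_strand))
    stop("strand must be '+' or '-', got: ", paste(bad_strand, collapse = ", "))
  if (any(is.na(tab$start)) || any(is.na(tab$end)) || any(tab$start < 1L) ||
      any(tab$end < tab$start))
    stop("genomic intervals must be 1-based with start <= end")

  # a probeset must be internally consistent (one group/role/event/gene)
  for (col in c("group", "role", "event_id", "gene_id")) {
    n_per_ps <- tapply(tab[[col]], tab$probeset_id,
                       function(x) length(unique(x)))
    if (any(n_per_ps > 1L))
      stop("probeset with inconsistent ", col, ": ",
           paste(names(n_per_ps)[n_per_ps > 1L], collapse = ", "))
  }
  # constitutive <=> event_id "."
  const <- tab$group == "constitutive"
  if (any(const & tab$event_id != "."))
    stop("constitutive probeset with an event_id: ",
         paste(unique(tab$probeset_id[const & tab$event_id != "."]), collapse = ", "))
  if (any(!const & tab$event_id == "."))
    stop("inclusion/exclusion probeset without an event: ",
         paste(unique(tab$probeset_id[!const & tab$event_id == "."]), collapse = ", "))
  if (any(const & tab$event_type != "."))
    stop("constitutive rows must carry event_type '.'")

  ev <- tab[!const, , drop = FALSE]
  if (nrow(ev)) {
    n_gene <- tapply(ev$gene_id, ev$event_id, function(x) length(unique(x)))
    if (any(n_gene > 1L))
      stop("event mapped to multiple genes: ",
           paste(names(n_gene)[n_gene > 1L], collapse = ", "))
    n_type <- tapply(ev$event_type, ev$event_id, function(x) length(unique(x)))
    if (any(n_type > 1L))
      stop("event with multiple event_types: ",
           paste(names(n_type)[n_type > 1L], collapse = ", "))
    ps_first <- ev[!duplicated(ev$probeset_id), , drop = FALSE]
    for (eid in unique(ps_first$event_id)) {
      e <- ps_first[ps_first$event_id == eid, , drop = FALSE]
      n_inc <- sum(e$group == "inclusion")
      n_exc <- sum(e$group == "exclusion")
      if (n_inc < 1L || n_exc < 1L)
        stop("event '", eid, "' lacks an ",
             if (n_inc < 1L) "inclusion" else "exclusion", " probeset")
      if (e$event_type[1L] == "cassette") {
        if (n_exc != 1L)
          stop("cassette event '", eid, "' must have exactly 1 exclusion ",
               "probeset, found ", n_exc)
        if (n_inc > 3L)
          stop("cassette event '", eid, "' has ", n_inc,
               " inclusion probesets (max 3: exon body + 2 junctions)")
      }
    }
  }
  # every gene carries at least one constitutive probeset
  genes_all <- unique(tab$gene_id)
  genes_const <- unique(tab$gene_id[const])
  orphan <- setdiff(genes_all, genes_const)
  if (length(orphan))
    stop("gene without a constitutive probeset: ",
         paste(orphan, collapse = ", "))
  invisible(tab)
}

#' Read an array design table
#'
#' Reads a tab-delimited, UTF-8 design file (one row per probe, \code{'#'}
#' comment lines ignored) and validates the full probe/probeset/event/gene
#' hierarchy. Coordinates in the file are 1-based inclusive.
#'
#' @param path path to a design TSV with the columns listed in
#'   \code{\link{ArrayDesign}}.
#' @return A validated \code{\link{ArrayDesign}}.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("no probes in design file '", path, "'")
  ArrayDesign(tab)
}

#' Write an array design table
#'
#' @param design an \code{\link{ArrayDesign}}.
#' @param path output TSV path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ArrayDesign"))
  utils::write.table(design$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.ArrayDesign <- function(x, ...) {
  cat("ArrayDesign:", nrow(x$genes), "genes,", nrow(x$events), "events,",
      nrow(x$probesets), "probesets,", nrow(x$probes), "probes\n")
  if (nrow(x$events))
    print(table(event_type = x$events$event_type))
  invisible(x)
}
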