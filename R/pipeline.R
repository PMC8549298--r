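#' Run the full assembly pipeline
#'
#' Drives overlap computation (or PAF import), clustering, per-cluster local
#' assembly / phasing / super-read construction, and global super-read
#' assembly into haplotigs. Per-cluster work is independent and can be
#' parallelised; results are combined in cluster-id order, so the output is
#' identical for any worker count given a fixed `rng_seed`.
#'
#' @param reads Read tibble ([read_sequences()] output) — must be non-empty.
#' @param params [assembly_params()].
#' @param overlaps Optional precomputed overlaps (e.g. [read_paf()] import);
#'   they still pass through [classify_and_filter()].
#' @param output_dir Optional directory: writes `contigs.fasta`,
#'   `superreads.fasta`, `manifest.json`.
#' @return An object of class `hb_assembly`: list with `contigs`,
#'   `super_reads`, `clusters`, `corrected_reads`, `manifest`, `params`.
#' @export
assemble_reads <- function(reads, params = assembly_params(), overlaps = NULL,
                           output_dir = NULL) {
  if (is.null(reads) || nrow(reads) == 0) {
    abort("no input reads: refusing to assemble an empty read set")
  }
  if (!"quality" %in% names(reads)) reads$quality <- NA_character_
  if (!"length" %in% names(reads)) reads$length <- nchar(reads$sequence)

  raw_ov <- overlaps %||% compute_overlaps(reads, params)
  ov <- classify_and_filter(raw_ov, params, keep_containments = TRUE)
  clusters <- build_clusters(reads, ov)
  cluster_ids <- sort(unique(clusters$cluster_id))

  run_one <- function(cl) {
    member_ids <- clusters$member_id[clusters$cluster_id == cl]
    members <- reads[match(member_ids, reads$id), , drop = FALSE]
    ov_sub <- ov[ov$query_id %in% member_ids & ov$target_id %in% member_ids, ,
                 drop = FALSE]
    cl_params <- params
    cl_params$rng_seed <- params$rng_seed + cl
    process_cluster(members, ov_sub, cl_params, cluster_id = cl)
  }
  results <- if (params$threads > 1) {
    parallel::mclapply(cluster_ids, run_one, mc.cores = params$threads,
                       mc.preschedule = FALSE)
  } else {
    lapply(cluster_ids, run_one)
  }
  for (i in seq_along(results)) {
    if (inherits(results[[i]], "try-error") || is.null(results[[i]])) {
      abort(sprintf("cluster %d failed during local assembly/phasing",
                    cluster_ids[i]))
    }
  }

  super_reads <- dplyr::bind_rows(lapply(results, `[[`, "super_reads"))
  corrected <- dplyr::bind_rows(lapply(results, `[[`, "corrected"))
  evidence <- dplyr::bind_rows(lapply(results, `[[`, "evidence"))
  cluster_stats <- dplyr::bind_rows(lapply(results, `[[`, "stats"))

  contigs <- tibble(id = character(), sequence = character(),
                    length = integer(), super_read_ids = list(),
                    n_super_reads = integer())
  polish_on <- FALSE
  if (nrow(super_reads) > 0) {
    srg <- build_super_read_graph(super_reads, params)
    if (params$snp_edge_filter) {
      srg <- absorb_redundant_super_reads(srg, super_reads, evidence, params)
      srg <- remove_spurious_edges_by_snps(srg, super_reads, evidence, params)
    }
    # transitive reduction precedes tip removal: transitive skip edges fake
    # branch points, which would make true chain ends look like tips
    srg <- remove_transitive_edges(srg)
    srg <- remove_tips(srg, params)
    contigs <- merge_simple_paths(srg, super_reads)
    if (params$snp_edge_filter && nrow(contigs) > 1) {
      contigs <- absorb_redundant_contigs(contigs, evidence, params)
    }
    # super-read end regions (thin cluster-edge coverage) become contig
    # interior at junctions; polishing with the full evidence set is the
    # step that repairs them, so it defaults to on
    polish_on <- params$polish_final %||% TRUE
    contigs <- polish_contigs(contigs, evidence, params,
                              do_polish = isTRUE(polish_on))
  }

  manifest <- list(
    params = unclass(params),
    input = list(n_reads = nrow(reads),
                 total_bases = sum(as.numeric(reads$length)),
                 checksum = rlang::hash(list(reads$id, reads$sequence))),
    stages = list(
      overlaps_raw = nrow(raw_ov),
      overlaps_kept = nrow(ov),
      clusters = length(cluster_ids),
      cluster_size_sum = nrow(clusters),
      super_reads = nrow(super_reads),
      contigs = nrow(contigs),
      final_polish = isTRUE(polish_on)
    )
  )
  res <- structure(list(contigs = contigs, super_reads = super_reads,
                        clusters = clusters, corrected_reads = corrected,
                        evidence_reads = evidence,
                        cluster_stats = cluster_stats,
                        manifest = manifest, params = params),
                   class = "hb_assembly")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$contigs, file.path(output_dir, "contigs.fasta"))
    srs <- res$super_reads
    if (nrow(srs) > 0) {
      srs_out <- tibble(id = sprintf("%s cluster=%d phase=%d", srs$id,
                                     srs$cluster_id, srs$phase),
                        sequence = srs$sequence)
      write_fasta(srs_out, file.path(output_dir, "superreads.fasta"))
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

# local assembly, phasing and super-read construction for one cluster
process_cluster <- function(members, ov_sub, params, cluster_id) {
  empty_sr <- tibble(id = character(), cluster_id = integer(),
                     phase = integer(), sequence = character(),
                     length = integer(), coverage = list(),
                     constituent_ids = list(), n_reads = integer())
  stats <- tibble(cluster_id = cluster_id, n_reads = nrow(members),
                  n_sites = 0L, mec_cost = NA_real_, n_h1 = 0L, n_h2 = 0L,
                  n_both = nrow(members))

  make_tbl <- function(sr, grp) {
    if (nrow(sr) == 0) return(NULL)
    tibble(sr_id = sr$id[1], read_id = grp$id, sequence = grp$sequence)
  }

  if (nrow(members) == 1) {
    if (members$length[1] < params$min_ovlp_len) {
      return(list(super_reads = empty_sr, corrected = NULL, evidence = NULL,
                  stats = stats))
    }
    sr <- build_super_read(members, params, cluster_id, phase = 0L)
    return(list(super_reads = sr, corrected = make_tbl(sr, members),
                evidence = make_tbl(sr, members), stats = stats))
  }

  backbone <- assemble_longest_path(members, ov_sub, params)$sequence
  polished <- as.character(polish(backbone, members, params))
  aln <- map_reads(polished, members, params)
  sites <- call_snps(aln, polished, params)

  groups <- list()
  if (nrow(sites) == 0) {
    groups[["0"]] <- members
  } else {
    am <- build_allele_matrix(aln, sites)
    ph <- solve_wmec(am, params)
    lab <- assign_unphased(members$id, ph)
    g1 <- members[members$id %in% lab$read_id[lab$label %in% c("H1", "both")], ,
                  drop = FALSE]
    g2 <- members[members$id %in% lab$read_id[lab$label %in% c("H2", "both")], ,
                  drop = FALSE]
    n1 <- sum(lab$label == "H1"); n2 <- sum(lab$label == "H2")
    stats$n_sites <- nrow(sites)
    stats$mec_cost <- ph$mec_cost
    stats$n_h1 <- n1; stats$n_h2 <- n2
    stats$n_both <- sum(lab$label == "both")
    if (n1 == 0 || n2 == 0) {
      groups[["0"]] <- members
    } else {
      groups[["1"]] <- g1
      groups[["2"]] <- g2
    }
  }

  srs <- list()
  corr <- list()
  evid <- list()
  for (ph_lab in names(groups)) {
    grp_raw <- groups[[ph_lab]]
    grp <- if (params$correct_raw_reads) {
      correct_group_reads(grp_raw, params)
    } else {
      grp_raw
    }
    # polish against the raw reads: corrected reads are consensus
    # projections with correlated errors, raw reads vote independently
    sr <- build_super_read(grp, params, cluster_id,
                           phase = as.integer(ph_lab),
                           polish_reads = grp_raw)
    if (nrow(grp) > 1) sr <- trim_super_read(sr, params)
    srs[[ph_lab]] <- sr
    corr[[ph_lab]] <- make_tbl(sr, grp)
    evid[[ph_lab]] <- make_tbl(sr, grp_raw)
  }
  list(super_reads = dplyr::bind_rows(srs),
       corrected = dplyr::bind_rows(corr),
       evidence = dplyr::bind_rows(evid),
       stats = stats)
}

#' @export
print.hb_assembly <- function(x, ...) {
  st <- x$manifest$stages
  cat("<hb_assembly>\n")
  cat(sprintf("  reads: %d   overlaps kept: %d   clusters: %d\n",
              x$manifest$input$n_reads, st$overlaps_kept, st$clusters))
  cat(sprintf("  super reads: %d   contigs: %d (total %d bp, N50 %s)\n",
              st$super_reads, nrow(x$contigs), sum(x$contigs$length),
              format(n50_value(x$contigs$length))))
  invisible(x)
}

#' @export
tidy.hb_assembly <- function(x, ...) {
  dplyr::select(x$contigs, -dplyr::any_of("sequence"))
}

#' @export
glance.hb_assembly <- function(x, ...) {
  tibble(n_reads = x$manifest$input$n_reads,
         n_clusters = x$manifest$stages$clusters,
         n_super_reads = x$manifest$stages$super_reads,
         n_contigs = nrow(x$contigs),
         total_len = sum(x$contigs$length),
         n50 = n50_value(x$contigs$length))
}
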