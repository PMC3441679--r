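# parameter hash for output headers (md5 of the deparse'd parameter list)
.paramHash <- function(params) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(paste(deparse(params), collapse = ""), tf)
    unname(tools::md5sum(tf))
}

#' Run the chromosome-enrichment pipeline end to end
#'
#' Composes the stages in their canonical order: standardize each replicate
#' log2-ratio track against the reference chromosome set, average the
#' replicates, median-smooth along chromosomes, then summarize per
#' chromosome and compute the X:autosome enrichment statistic; in parallel,
#' build TSS/TES meta-gene profiles stratified by expression quintile and
#' chromosome class, and the center-anchored intergenic profile over long
#' annotation-free regions. Raw-count chip/input pairs are first converted
#' with [log2Ratio()].
#'
#' @param tracks list of replicate [SignalTrack-class] log2-ratio tracks
#'   (or raw-count chip tracks if `inputTracks` is given).
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param expression named numeric expression vector.
#' @param genome a [GenomeBuild-class].
#' @param inputTracks optional list of raw-count input tracks matching
#'   `tracks`.
#' @param reference standardization reference, `"autosomes"` or `"all"`.
#' @param pseudocount pseudocount for the raw-count path.
#' @param smoothWindow median smoothing window, bp (default 1 kb).
#' @param tssWindow,tesWindow `c(upstream, downstream)` bp around the TSS
#'   (default 1 kb/1 kb) and TES (default 1.5 kb/1 kb).
#' @param profileBin profile bin width, bp (default 50).
#' @param intergenicMinLength minimum intergenic region length, bp (default
#'   10 kb).
#' @param intergenicFlank intergenic profile half-window, bp (default 5 kb).
#' @param quantileScope expression ranking scope, see [assignGroups()].
#' @param outDir optional directory; when given, writes the standardized
#'   averaged track (bedGraph), chromosome summary, profile TSVs,
#'   intergenic BED and a JSON run manifest. Every table carries a header
#'   naming the producing stage and the parameter hash.
#' @return (invisibly when writing) a list with elements `track` (the
#'   standardized, averaged, smoothed [SignalTrack-class]), `summary`,
#'   `xaEnrichment`, `groups`, `tssProfile`, `tesProfile`, `intergenic`,
#'   `intergenicProfile` and `manifest`.
#' @export
runEnrichmentPipeline <- function(tracks, genes, expression, genome,
        inputTracks = NULL, reference = c("autosomes", "all"),
        pseudocount = 1, smoothWindow = 1000,
        tssWindow = c(1000, 1000), tesWindow = c(1500, 1000),
        profileBin = 50, intergenicMinLength = 10000,
        intergenicFlank = 5000,
        quantileScope = c("per-class", "global"), outDir = NULL) {
    reference <- match.arg(reference)
    quantileScope <- match.arg(quantileScope)
    params <- list(reference = reference, pseudocount = pseudocount,
                   smoothWindow = smoothWindow, tssWindow = tssWindow,
                   tesWindow = tesWindow, profileBin = profileBin,
                   intergenicMinLength = intergenicMinLength,
                   intergenicFlank = intergenicFlank,
                   quantileScope = quantileScope)
    hash <- .paramHash(params)
    stages <- character(0)
    warningsSeen <- character(0)
    note <- function(stage) stages <<- c(stages, stage)
    run <- function(stage, expr) {
        withCallingHandlers(
            tryCatch(expr, error = function(e)
                stop("stage '", stage, "' failed: ", conditionMessage(e),
                     call. = FALSE)),
            warning = function(w) {
                warningsSeen <<- c(warningsSeen,
                                   paste0(stage, ": ", conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
    }
    if (!is.null(inputTracks)) {
        note("log2_ratio")
        tracks <- run("log2_ratio", mapply(log2Ratio, tracks, inputTracks,
            MoreArgs = list(pseudocount = pseudocount), SIMPLIFY = FALSE))
    }
    note("standardize")
    ztracks <- run("standardize",
                   lapply(tracks, standardize, reference = reference))
    note("average_replicates")
    avg <- run("average_replicates", averageTracks(ztracks))
    note("median_smooth")
    smoothed <- run("median_smooth", medianSmooth(avg, smoothWindow))
    note("chromosome_summary")
    summary <- run("chromosome_summary", chromosomeSummary(smoothed))
    xa <- run("xa_enrichment", xaEnrichment(smoothed))
    note("gene_groups")
    groups <- run("gene_groups",
                  assignGroups(expression, genes, genome,
                               quantileScope = quantileScope))
    note("tss_profile")
    tssPM <- run("tss_profile",
                 anchoredProfile(avg, genes, "TSS", tssWindow[1],
                                 tssWindow[2], profileBin))
    tssProf <- run("tss_profile", profileSummary(tssPM, groups))
    note("tes_profile")
    tesPM <- run("tes_profile",
                 anchoredProfile(avg, genes, "TES", tesWindow[1],
                                 tesWindow[2], profileBin))
    tesProf <- run("tes_profile", profileSummary(tesPM, groups))
    note("intergenic")
    regions <- run("intergenic",
                   findIntergenic(genes, genome, intergenicMinLength))
    igProf <- run("intergenic_profile",
                  intergenicProfile(avg, regions, intergenicFlank,
                                    profileBin))
    manifest <- list(parameters = params, parameterHash = hash,
                     stages = stages, warnings = warningsSeen,
                     nGenes = length(genes), nReplicates = length(tracks),
                     chromosomes = as.list(chromLengths(genome)),
                     xaEnrichment = xa)
    result <- list(track = smoothed, summary = summary, xaEnrichment = xa,
                   groups = groups, tssProfile = tssProf,
                   tesProfile = tesProf, intergenic = regions,
                   intergenicProfile = igProf, manifest = manifest)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeTrack(smoothed, file.path(outDir, "standardized_smoothed.bedGraph"))
        hdr <- function(stage) sprintf("xachrom %s params=%s", stage, hash)
        writeTsv <- function(df, file, stage) {
            con <- file(file.path(outDir, file), "w")
            writeLines(paste0("# ", hdr(stage)), con)
            write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
            close(con)
        }
        writeTsv(summary, "chromosome_summary.tsv", "chromsummary")
        writeTsv(tssProf, "tss_profile.tsv", "profile-tss")
        writeTsv(tesProf, "tes_profile.tsv", "profile-tes")
        writeTsv(igProf, "intergenic_profile.tsv", "profile-intergenic")
        writeIntergenic(regions, file.path(outDir, "intergenic"))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        return(invisible(result))
    }
    result
}
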