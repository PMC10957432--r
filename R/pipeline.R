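#' Run the full processing pipeline on one tracing file
#'
#' Convenience wrapper chaining the stages: parse the tall CSV into a
#' raw record, combine sensors, repair the FHR, detect patterns, and
#' extract per-epoch features.  Each intermediate is returned so any
#' stage can be inspected or persisted.
#'
#' @param path tall tracing CSV path.
#' @param repair_cfg a [repair_config()].
#' @param pattern_cfg a [pattern_config()].
#' @param feature_cfg a [feature_config()].
#' @param catalog optional `ctg_catalog`; when given, each stage is
#'   recorded.
#' @return a list: `status`, `parse_report`, `raw`, `combined`,
#'   `repaired`, `noi`, `events`, `epochs`, `features`.
#' @export
process_tracing <- function(path,
                            repair_cfg = repair_config(),
                            pattern_cfg = pattern_config(),
                            feature_cfg = feature_config(),
                            catalog = NULL) {
  parsed <- parse_tracing_csv(path)
  if (is.null(parsed$record))
    return(list(status = parsed$status, parse_report = parsed$report))
  raw <- parsed$record
  combined <- combine_sensors(raw)
  rep <- repair_record(combined, repair_cfg)
  events <- detect_patterns(rep$record, rep$noi, pattern_cfg)
  epochs <- segment_epochs(rep$record, rep$noi, feature_cfg)
  feats <- extract_features(rep$record, events, rep$noi, feature_cfg)
  if (!is.null(catalog)) {
    write_catalog(catalog, raw)
    write_catalog(catalog, combined)
    write_catalog(catalog, rep$record, events = events,
                  features = feats)
  }
  list(status = "ok", parse_report = parsed$report, raw = raw,
       combined = combined, repaired = rep$record, noi = rep$noi,
       events = events, epochs = epochs, features = feats)
}
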