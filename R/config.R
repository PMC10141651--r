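## YAML configuration mirroring NetworkConfig and TrainConfig field-for-field.

#' Read network and training configuration from YAML
#'
#' The file may contain a `network:` block (NetworkConfig fields) and a
#' `train:` block (TrainConfig fields); missing fields take the package
#' defaults.
#'
#' @param path YAML file.
#' @return list with `network` (\linkS4class{NetworkConfig}) and `train`
#'   (\linkS4class{TrainConfig}).
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  list(network = do.call(networkConfig, as.list(y$network)),
       train = do.call(trainConfig, as.list(y$train)))
}

#' Write network and training configuration to YAML
#'
#' @param netCfg a \linkS4class{NetworkConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeConfig <- function(netCfg, trainCfg, path) {
  slots_of <- function(x) {
    out <- lapply(slotNames(class(x)), function(s) slot(x, s))
    names(out) <- slotNames(class(x))
    out
  }
  yaml::write_yaml(list(network = slots_of(netCfg), train = slots_of(trainCfg)),
                   path)
  invisible(path)
}
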