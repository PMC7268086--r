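#' Idealized MEG sensor array on a hemispherical helmet
#'
#' Places \code{n_channels} radial magnetometers quasi-uniformly on the upper
#' hemisphere of a sphere of radius \code{sensor_radius} using a
#' deterministic Fibonacci spiral. The conductor (head) is a concentric
#' sphere of radius \code{head_radius}. Radial magnetometers on a spherical
#' conductor preserve the structure of the MEG inverse problem while keeping
#' the forward model closed-form.
#'
#' @param n_channels number of magnetometers (>= 16).
#' @param sensor_radius helmet radius in meters; must exceed
#'   \code{head_radius}.
#' @param head_radius conductor sphere radius in meters.
#' @return An object of class \code{sensor_array} with elements
#'   \code{n_channels}, \code{positions} (n x 3, meters),
#'   \code{orientations} (n x 3 radial unit vectors), \code{sensor_radius},
#'   \code{head_radius}.
#' @examples
#' arr <- make_sensor_array(102, 0.12, 0.09)
#' range(sqrt(rowSums(arr$positions^2)))  # all at 0.12
#' @export
make_sensor_array <- function(n_channels = 102, sensor_radius = 0.12,
                              head_radius = 0.09) {
  if (n_channels < 16)
    stop_megdmn("n_channels must be at least 16 (got %d)", n_channels,
                class = "megdmn_config_error")
  if (!(sensor_radius > head_radius && head_radius > 0))
    stop_megdmn("need sensor_radius > head_radius > 0",
                class = "megdmn_config_error")
  i <- seq_len(n_channels)
  zf <- 1 - (i - 0.5) / n_channels        # in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))           # golden angle
  rho <- sqrt(pmax(0, 1 - zf^2))
  ori <- cbind(rho * cos(phi), rho * sin(phi), zf)
  structure(list(n_channels = as.integer(n_channels),
                 positions = sensor_radius * ori,
                 orientations = ori,
                 sensor_radius = sensor_radius,
                 head_radius = head_radius),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d radial magnetometers, helmet %.3f m, head %.3f m\n",
              x$n_channels, x$sensor_radius, x$head_radius))
  invisible(x)
}

validate_sensor_array <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  pr <- sqrt(rowSums(array$positions^2))
  if (max(abs(pr - array$sensor_radius)) > 1e-9)
    stop_megdmn("sensor positions not on the helmet sphere",
                class = "megdmn_validity_error")
  onorm <- sqrt(rowSums(array$orientations^2))
  if (max(abs(onorm - 1)) > 1e-12)
    stop_megdmn("sensor orientations not unit norm",
                class = "megdmn_validity_error")
  invisible(array)
}
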