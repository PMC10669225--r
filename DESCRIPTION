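Package: artikin
Title: Personalized Virtual Dental Articulator from CT Landmarks and Jaw-Motion Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Models mandibular motion as a virtual dental articulator built
    from anatomy-derived landmarks (a virtual facebow on the Frankfurt or
    Camper reference plane), personalizes the condylar path from optically
    tracked jaw motion (sagittal quadratic, horizontal Bennett line and a
    NURBS space curve), solves the 6-DOF mandibular pose from incisal-edge
    targets by Newton-Raphson inverse kinematics under condylar-path
    constraints, plays back dynamic occlusion with sphere-proxy collision
    handling, and verifies simulated against tracked condylar trajectories
    with the average trajectory error and the discrete Frechet distance.
    Includes a synthetic-patient generator emulating CT and optical-tracking
    outputs, rigid registration (Kabsch, ICP), STL/PLY mesh input and a
    command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
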