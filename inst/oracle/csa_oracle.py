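#!/usr/bin/env python
"""Independent reference implementation of constant-solid-angle q-ball ODFs.

Reads gradient directions, diffusion signals and evaluation directions from
CSV, fits ln(-ln(S/S0)) in a real even-order spherical-harmonic basis built
from scipy's complex spherical harmonics, applies the per-degree CSA
transform (-l(l+1) * 2*pi*P_l(0) / (16*pi^2), l=0 term 1/sqrt(4*pi)), and
writes the ODF values at the evaluation directions. Shares no code or basis
convention with the R implementation; agreement follows because the fitted
function, and the per-degree CSA operator, are invariant to the choice of
real orthonormal basis.

Usage:
  python csa_oracle.py dirs.csv signals.csv s0.csv evaldirs.csv out.csv \
      [L] [epsilon]
"""
import sys

import numpy as np
from numpy.polynomial.legendre import Legendre
from scipy.special import sph_harm_y


def real_sh_basis(order, dirs):
    """Real symmetric SH basis (even degrees 0..order) at unit vectors."""
    theta = np.arccos(np.clip(dirs[:, 2], -1.0, 1.0))   # polar
    phi = np.arctan2(dirs[:, 1], dirs[:, 0])            # azimuth
    cols = []
    degrees = []
    for l in range(0, order + 1, 2):
        for m in range(-l, l + 1):
            y = sph_harm_y(l, abs(m), theta, phi)
            if m < 0:
                col = np.sqrt(2.0) * (-1.0) ** m * y.imag
            elif m == 0:
                col = y.real
            else:
                col = np.sqrt(2.0) * (-1.0) ** m * y.real
            cols.append(col)
            degrees.append(l)
    return np.column_stack(cols), np.asarray(degrees)


def legendre_at_zero(l):
    c = np.zeros(l + 1)
    c[l] = 1.0
    return Legendre(c)(0.0)


def main(argv):
    dirs = np.loadtxt(argv[1], delimiter=",", ndmin=2)
    sig = np.loadtxt(argv[2], delimiter=",", ndmin=2)
    s0 = np.loadtxt(argv[3], delimiter=",", ndmin=1)
    evald = np.loadtxt(argv[4], delimiter=",", ndmin=2)
    out_path = argv[5]
    order = int(argv[6]) if len(argv) > 6 else 4
    eps = float(argv[7]) if len(argv) > 7 else 1e-3

    att = np.clip(sig / s0[:, None], eps, 1.0 - eps)
    y = np.log(-np.log(att))

    basis, degrees = real_sh_basis(order, dirs)
    coef, *_ = np.linalg.lstsq(basis, y.T, rcond=None)   # ncoef x nvox

    mult = np.array([-l * (l + 1) * 2.0 * np.pi * legendre_at_zero(l)
                     / (16.0 * np.pi ** 2) for l in degrees])
    odf_coef = coef * mult[:, None]
    odf_coef[degrees == 0, :] = 1.0 / np.sqrt(4.0 * np.pi)

    eval_basis, _ = real_sh_basis(order, evald)
    odf = (eval_basis @ odf_coef).T                      # nvox x neval
    np.savetxt(out_path, odf, delimiter=",")


if __name__ == "__main__":
    main(sys.argv)
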