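/* Compiled vector field and Jacobian of the normalized NF-kB model for
 * deSolve's compiled-function interface. State ordering and parameter
 * layout mirror the R reference implementation (rhs_core / jac_core):
 *
 *   y = K, N, G_I, R_I, I, G_A, R_A, A [, G_g1, R_g1, ...]
 *   parms = S, pv[21] (kinetic rates in .kinetic_names order),
 *           n_genes, then 5 rates per gene
 *           (k_on_G, k_on0_G, k_off_G, k_off0_G, d_R_G).
 *
 * S is constant within a call: the R driver integrates piecewise between
 * forcing switch times.
 */

#include <R.h>
#include <math.h>

#define MAX_PARMS 543  /* 23 + 5 * 104 genes */

static double parms[MAX_PARMS];

void nfkb_init(void (*odeparms)(int *, double *))
{
    int n = MAX_PARMS;
    odeparms(&n, parms);
}

void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double S = parms[0];
    const double *pv = parms + 1;   /* pv[0] == d_K ... pv[20] == d_A */
    const double K = y[0], N = y[1], G_I = y[2], R_I = y[3];
    const double I = y[4], G_A = y[5], R_A = y[6], A = y[7];
    int ng = (int) parms[22];
    int j;

    ydot[0] = -pv[0] * K + S / (1.0 + pow(A, pv[1]));
    ydot[1] = pv[2] * (1.0 - N) + pv[3] * pv[4] * (1.0 - N) +
              pv[5] * K * (1.0 - N) - pv[6] * I * N;
    ydot[2] = (pv[10] * N + pv[11]) * (1.0 - G_I) -
              (pv[12] * I + pv[13]) * G_I;
    ydot[3] = pv[9] * (G_I - R_I);
    ydot[4] = pv[2] * (1.0 - N) - pv[7] * pv[5] * K * I - pv[6] * I * N +
              pv[8] * R_I - pv[4] * I;
    ydot[5] = (pv[14] * N + pv[15]) * (1.0 - G_A) -
              (pv[16] * I + pv[17]) * G_A;
    ydot[6] = pv[18] * (G_A - R_A);
    ydot[7] = pv[19] * R_A - pv[20] * A;

    for (j = 0; j < ng; j++) {
        const double *g = parms + 23 + 5 * j;
        const double G = y[8 + 2 * j], Rg = y[9 + 2 * j];
        ydot[8 + 2 * j] = (g[0] * N + g[1]) * (1.0 - G) -
                          (g[2] * I + g[3]) * G;
        ydot[9 + 2 * j] = g[4] * (G - Rg);
    }
}

/* Full Jacobian, column-major: pd[j * nrowpd + i] = d f_i / d y_j */
void nfkb_jac(int *neq, double *t, double *y, int *ml, int *mu,
              double *pd, int *nrowpd, double *yout, int *ip)
{
    const double S = parms[0];
    const double *pv = parms + 1;
    const double K = y[0], N = y[1], G_I = y[2];
    const double I = y[4], G_A = y[5], A = y[7];
    const int nr = *nrowpd, m = *neq;
    int ng = (int) parms[22];
    int i, j;
    double n = pv[1], An = pow(A, n);

    for (j = 0; j < m; j++)
        for (i = 0; i < nr; i++)
            pd[j * nr + i] = 0.0;

#define PD(i, j) pd[(j) * nr + (i)]
    PD(0, 0) = -pv[0];
    PD(0, 7) = -S * n * pow(A, n - 1.0) / ((1.0 + An) * (1.0 + An));
    PD(1, 0) = pv[5] * (1.0 - N);
    PD(1, 1) = -pv[2] - pv[3] * pv[4] - pv[5] * K - pv[6] * I;
    PD(1, 4) = -pv[6] * N;
    PD(2, 1) = pv[10] * (1.0 - G_I);
    PD(2, 2) = -(pv[10] * N + pv[11]) - (pv[12] * I + pv[13]);
    PD(2, 4) = -pv[12] * G_I;
    PD(3, 2) = pv[9];
    PD(3, 3) = -pv[9];
    PD(4, 0) = -pv[7] * pv[5] * I;
    PD(4, 1) = -pv[2] - pv[6] * I;
    PD(4, 3) = pv[8];
    PD(4, 4) = -pv[7] * pv[5] * K - pv[6] * N - pv[4];
    PD(5, 1) = pv[14] * (1.0 - G_A);
    PD(5, 5) = -(pv[14] * N + pv[15]) - (pv[16] * I + pv[17]);
    PD(5, 4) = -pv[16] * G_A;
    PD(6, 5) = pv[18];
    PD(6, 6) = -pv[18];
    PD(7, 6) = pv[19];
    PD(7, 7) = -pv[20];

    for (j = 0; j < ng; j++) {
        const double *g = parms + 23 + 5 * j;
        const int iG = 8 + 2 * j, iR = 9 + 2 * j;
        const double G = y[iG];
        PD(iG, 1) = g[0] * (1.0 - G);
        PD(iG, iG) = -(g[0] * N + g[1]) - (g[2] * I + g[3]);
        PD(iG, 4) = -g[2] * G;
        PD(iR, iG) = g[4];
        PD(iR, iR) = -g[4];
    }
#undef PD
}
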