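/* Compiled right-hand side of the coupled awareness-epidemic model, for use
 * with deSolve's compiled-model interface. Mirrors the R reference
 * implementation (info_rhs / full_rhs) exactly; the test suite asserts
 * agreement between the two routes.
 *
 * State layout (column-major, matching the R array [level, disease, group]):
 *   y[lev + dis*(K+1) + grp*3*(K+1)]
 * with lev = 0..K-1 the finite awareness levels, lev = K the unaware
 * reservoir, dis = 0,1,2 for S,I,R and grp = 0,1 for trusting,distrusting.
 */

#include <R.h>
#include <R_ext/Rdynload.h>
#include <stdlib.h>

/* beta, sigma, rho, alpha_T, alpha_D, lambda, omega, N, K, stop_threshold */
static double parms[10];

void aware_initmod(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

#define IDX(lev, dis, grp) ((lev) + (dis) * (K + 1) + (grp) * 3 * (K + 1))

/* terminal root: total infected falls below the stop threshold, i.e. the
 * epidemic is over; stopping here avoids chasing the infected compartments
 * down into the denormal range */
void aware_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    const int K = (int) parms[8];
    double I = 0.0;
    for (int grp = 0; grp < 2; grp++)
        for (int lev = 0; lev <= K; lev++)
            I += y[IDX(lev, 1, grp)];
    gout[0] = I - parms[9];
}

void aware_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double beta = parms[0], sigma = parms[1], rho = parms[2];
    const double aT = parms[3] / parms[7], aD = parms[4] / parms[7];
    const double lambda = parms[5], omega = parms[6];
    const int K = (int) parms[8];
    int lev, dis, grp;

    /* scratch space reused across calls; resized only when K changes */
    static double *work = NULL;
    static int work_K = -1;
    if (K != work_K) {
        free(work);
        work = (double *) malloc((size_t)(4 * (K + 1) + K) * sizeof(double));
        if (work == NULL) error("awaresir: scratch allocation failed");
        work_K = K;
    }
    double *nlev = work;
    double *CS = nlev + K;           /* CS[m] = sum of nlev over levels < m */
    double *TS = CS + (K + 1);       /* TS[m] = sum of nlev over levels >= m */
    double *pf = TS + (K + 1);       /* protection factors, levels 0..K-1, inf */
    double *buf = pf + (K + 1);

    for (lev = 0; lev < *neq; lev++) ydot[lev] = 0.0;

    double n_inf = 0.0;
    for (lev = 0; lev < K; lev++) nlev[lev] = 0.0;
    for (grp = 0; grp < 2; grp++)
        for (dis = 0; dis < 3; dis++) {
            for (lev = 0; lev < K; lev++) nlev[lev] += y[IDX(lev, dis, grp)];
            n_inf += y[IDX(K, dis, grp)];
        }
    CS[0] = 0.0;
    for (lev = 0; lev < K; lev++) CS[lev + 1] = CS[lev] + nlev[lev];
    TS[K] = 0.0;
    for (lev = K - 1; lev >= 0; lev--) TS[lev] = TS[lev + 1] + nlev[lev];

    /* information exchange and fading, every disease state alike */
    for (dis = 0; dis < 3; dis++) {
        /* trusting: recipient at level j adopts a source at i <= j-2,
         * landing at i+1; unaware recipients accept sources i <= K-2 */
        double *xT = y + IDX(0, dis, 0);
        double *dT = ydot + IDX(0, dis, 0);
        double xT_inf = xT[K];
        /* tail[m] = sum of xT over finite levels > m */
        double *tail = buf;
        tail[K - 1] = 0.0;
        for (lev = K - 2; lev >= 0; lev--) tail[lev] = tail[lev + 1] + xT[lev + 1];
        for (lev = 2; lev < K; lev++)
            dT[lev] -= aT * xT[lev] * CS[lev - 1];
        dT[K] -= aT * xT_inf * CS[K - 1];
        for (lev = 1; lev < K; lev++)
            dT[lev] += aT * nlev[lev - 1] * (tail[lev] + xT_inf);

        /* distrusting: recipient at level j adopts a source at i >= j+1
         * (including the unaware reservoir), landing at i+1, Inf+1 = Inf */
        double *xD = y + IDX(0, dis, 1);
        double *dD = ydot + IDX(0, dis, 1);
        /* BY[m] = sum of xD over levels < m */
        double *BY = buf;
        BY[0] = 0.0;
        for (lev = 0; lev < K; lev++) BY[lev + 1] = BY[lev] + xD[lev];
        for (lev = 0; lev < K; lev++)
            dD[lev] -= aD * xD[lev] * (TS[lev + 1] + n_inf);
        for (lev = 1; lev < K; lev++)
            dD[lev] += aD * nlev[lev - 1] * BY[lev - 1];
        dD[K] += aD * (nlev[K - 1] * BY[K - 1] + n_inf * BY[K]);

        /* fading: one level per event, K-1 fades into the reservoir */
        for (grp = 0; grp < 2; grp++) {
            double *x = y + IDX(0, dis, grp);
            double *dx = ydot + IDX(0, dis, grp);
            for (lev = 0; lev < K; lev++) dx[lev] -= lambda * x[lev];
            for (lev = 1; lev < K; lev++) dx[lev] += lambda * x[lev - 1];
            dx[K] += lambda * x[K - 1];
        }
    }

    /* disease dynamics */
    for (lev = 0; lev < K; lev++) pf[lev] = 1.0 - pow(rho, (double) lev);
    pf[K] = 1.0;
    double phi = 0.0;
    for (lev = 0; lev <= K; lev++)
        phi += pf[lev] * (y[IDX(lev, 1, 0)] + y[IDX(lev, 1, 1)]);
    const double binf = beta * phi / parms[7];

    for (grp = 0; grp < 2; grp++) {
        double refresh = 0.0;
        for (lev = 0; lev <= K; lev++) {
            double new_inf = binf * pf[lev] * y[IDX(lev, 0, grp)];
            ydot[IDX(lev, 0, grp)] -= new_inf;
            ydot[IDX(lev, 1, grp)] += new_inf;
            double recov = sigma * y[IDX(lev, 1, grp)];
            ydot[IDX(lev, 1, grp)] -= recov;
            ydot[IDX(lev, 2, grp)] += recov;
            if (lev >= 1) {
                double r = omega * y[IDX(lev, 1, grp)];
                ydot[IDX(lev, 1, grp)] -= r;
                refresh += r;
            }
        }
        ydot[IDX(0, 1, grp)] += refresh;
    }
}

static const R_CMethodDef CEntries[] = {
    {"aware_initmod", (DL_FUNC) &aware_initmod, 1},
    {"aware_derivs",  (DL_FUNC) &aware_derivs,  6},
    {"aware_root",    (DL_FUNC) &aware_root,    7},
    {NULL, NULL, 0}
};

void R_init_awaresir(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
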